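#' Parameters of a dynamic N-mixture model
#'
#' Bundles the three coefficient vectors of the model, each starting with an
#' intercept and followed by the coefficients of the terms the model includes,
#' in canonical term order (see [nmix_spec()]):
#'
#' * `beta_psi` — log initial abundance: intercept, then `climate`;
#' * `beta_lambda` — log growth rate: intercept, then any of `climate`,
#'   `treatment`, `density`, `density2`, `climate2`, `climate:density`;
#' * `beta_p` — logit detection: intercept, then any of `wind`, `noise`,
#'   `date`, `time`.
#'
#' @param beta_psi,beta_lambda,beta_p Numeric coefficient vectors.
#' @return An object of class `nmix_params`.
#' @examples
#' nmix_params(beta_psi = c(-2.63, -1.56),
#'             beta_lambda = c(-1.08, -0.75, -1.46, -0.24),
#'             beta_p = c(0.37, 0.23, -0.57, 0.51, -0.13))
#' @export
nmix_params <- function(beta_psi = 0, beta_lambda = 0, beta_p = 0) {
  stopifnot(is.numeric(beta_psi), is.numeric(beta_lambda), is.numeric(beta_p),
            length(beta_psi) >= 1, length(beta_lambda) >= 1, length(beta_p) >= 1)
  structure(list(beta_psi = as.numeric(beta_psi),
                 beta_lambda = as.numeric(beta_lambda),
                 beta_p = as.numeric(beta_p)),
            class = "nmix_params")
}

#' @export
print.nmix_params <- function(x, ...) {
  cat("<nmix_params>\n")
  cat("  beta_psi:   ", paste(signif(x$beta_psi, 4), collapse = ", "), "\n")
  cat("  beta_lambda:", paste(signif(x$beta_lambda, 4), collapse = ", "), "\n")
  cat("  beta_p:     ", paste(signif(x$beta_p, 4), collapse = ", "), "\n")
  invisible(x)
}

# coefficient names implied by a spec, concatenated in C++ layout order
param_names <- function(spec) {
  c(paste0("psi_", c("(Intercept)", spec$psi_terms)),
    paste0("lambda_", c("(Intercept)", spec$lambda_terms)),
    paste0("p_", c("(Intercept)", spec$p_terms)))
}

# validate lengths against a spec and flatten to the C++ layout
param_vector <- function(params, spec) {
  stopifnot(inherits(params, "nmix_params"), inherits(spec, "nmix_spec"))
  want <- c(1 + length(spec$psi_terms), 1 + length(spec$lambda_terms),
            1 + length(spec$p_terms))
  got <- c(length(params$beta_psi), length(params$beta_lambda),
           length(params$beta_p))
  if (!all(want == got)) {
    stop(sprintf(
      "parameter lengths (%s) do not match spec term counts + intercepts (%s)",
      paste(got, collapse = ","), paste(want, collapse = ",")))
  }
  setNames(c(params$beta_psi, params$beta_lambda, params$beta_p),
           param_names(spec))
}

# 0/1 indicators of lambda terms (and psi climate) in the fixed C++ order
spec_flags <- function(spec) {
  as.integer(c("climate" %in% spec$psi_terms,
               "climate" %in% spec$lambda_terms,
               "treatment" %in% spec$lambda_terms,
               "density" %in% spec$lambda_terms,
               "density2" %in% spec$lambda_terms,
               "climate2" %in% spec$lambda_terms,
               "climate:density" %in% spec$lambda_terms))
}

# split a flat coefficient vector back into the three blocks
param_unflatten <- function(beta, spec) {
  n1 <- 1 + length(spec$psi_terms)
  n2 <- 1 + length(spec$lambda_terms)
  n3 <- 1 + length(spec$p_terms)
  stopifnot(length(beta) == n1 + n2 + n3)
  nmix_params(beta_psi = beta[seq_len(n1)],
              beta_lambda = beta[n1 + seq_len(n2)],
              beta_p = beta[n1 + n2 + seq_len(n3)])
}
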