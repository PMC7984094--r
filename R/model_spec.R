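LAMBDA_TERMS <- c("climate", "treatment", "density", "density2", "climate2",
                  "climate:density")
PSI_TERMS <- "climate"
P_TERMS <- c("wind", "noise", "date", "time")

#' Model specification for a dynamic N-mixture model
#'
#' Declares which covariate terms enter each of the three linear predictors:
#' initial abundance (`psi`, log link), population growth rate (`lambda`, log
#' link) and detection probability (`p`, logit link). Quadratic and
#' interaction terms require their main effects.
#'
#' @param psi_terms Character vector, subset of `"climate"` (empty =
#'   intercept-only).
#' @param lambda_terms Character vector, subset of `climate`, `treatment`,
#'   `density`, `density2`, `climate2`, `climate:density`.
#' @param p_terms Character vector, subset of `wind`, `noise`, `date`, `time`.
#' @param label Optional model label; derived from the terms if omitted.
#' @return An object of class `nmix_spec`.
#' @examples
#' nmix_spec(lambda_terms = c("climate", "treatment", "density"))
#' @export
nmix_spec <- function(psi_terms = "climate",
                      lambda_terms = character(),
                      p_terms = c("wind", "noise", "date", "time"),
                      label = NULL) {
  psi_terms <- unique(as.character(psi_terms))
  lambda_terms <- unique(as.character(lambda_terms))
  p_terms <- unique(as.character(p_terms))

  bad <- setdiff(psi_terms, PSI_TERMS)
  if (length(bad)) stop("unknown psi term(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(lambda_terms, LAMBDA_TERMS)
  if (length(bad)) stop("unknown lambda term(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(p_terms, P_TERMS)
  if (length(bad)) stop("unknown p term(s): ", paste(bad, collapse = ", "))

  if ("density2" %in% lambda_terms && !"density" %in% lambda_terms) {
    stop("'density2' requires the 'density' main effect")
  }
  if ("climate2" %in% lambda_terms && !"climate" %in% lambda_terms) {
    stop("'climate2' requires the 'climate' main effect")
  }
  if ("climate:density" %in% lambda_terms &&
      !all(c("climate", "density") %in% lambda_terms)) {
    stop("'climate:density' requires both main effects")
  }

  lambda_terms <- LAMBDA_TERMS[LAMBDA_TERMS %in% lambda_terms]
  p_terms <- P_TERMS[P_TERMS %in% p_terms]

  spec <- structure(
    list(psi_terms = psi_terms, lambda_terms = lambda_terms,
         p_terms = p_terms, label = label %||% NA_character_),
    class = "nmix_spec"
  )
  if (is.na(spec$label)) spec$label <- spec_label(spec)
  spec
}

spec_label <- function(spec) {
  fmt <- function(terms, int_x = FALSE) {
    if (!length(terms)) return(".")
    shown <- terms
    # collapse "climate + density + climate:density" to "climate x density"
    if ("climate:density" %in% terms) {
      shown <- setdiff(shown, c("climate", "density", "climate:density"))
      shown <- c("climate x density", shown)
    }
    shown <- sub("density2", "density^2", shown, fixed = TRUE)
    shown <- sub("climate2", "climate^2", shown, fixed = TRUE)
    paste(shown, collapse = " + ")
  }
  paste0("N1(", fmt(spec$psi_terms), ") lambda(", fmt(spec$lambda_terms), ")")
}

#' @export
print.nmix_spec <- function(x, ...) {
  cat("<nmix_spec>", x$label, "\n")
  cat("  psi    ~", if (length(x$psi_terms)) paste(x$psi_terms, collapse = " + ") else ".", "\n")
  cat("  lambda ~", if (length(x$lambda_terms)) paste(x$lambda_terms, collapse = " + ") else ".", "\n")
  cat("  p      ~", if (length(x$p_terms)) paste(x$p_terms, collapse = " + ") else ".", "\n")
  invisible(x)
}

#' Parse a compact model-formula string
#'
#' Grammar: up to three `;`-separated clauses `psi ~ <terms>`,
#' `lambda ~ <terms>`, `p ~ <terms>`, with `+`-separated terms from the
#' allowed vocabulary and `.` for intercept-only. `climate * density` expands
#' to both main effects plus the interaction; `density2`/`density^2` is the
#' quadratic term. Omitted clauses default to `psi ~ climate` and
#' `p ~ wind + noise + date + time` (the full detection model), and
#' `lambda ~ .`.
#'
#' @param formula A string such as
#'   `"lambda ~ climate + treatment + density"`.
#' @return An [nmix_spec()].
#' @examples
#' parse_model("lambda ~ climate + treatment + density")
#' parse_model("psi ~ .; lambda ~ .")
#' @export
parse_model <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1)
  clauses <- strsplit(formula, ";", fixed = TRUE)[[1]]
  parts <- list(psi = "climate", lambda = character(),
                p = c("wind", "noise", "date", "time"))
  for (cl in clauses) {
    cl <- trimws(cl)
    if (cl == "") next
    m <- regmatches(cl, regexec("^(psi|lambda|p)\\s*~\\s*(.*)$", cl))[[1]]
    if (length(m) != 3) stop("cannot parse clause: '", cl, "'")
    parts[[m[2]]] <- parse_terms(m[3])
  }
  nmix_spec(psi_terms = parts$psi, lambda_terms = parts$lambda,
            p_terms = parts$p)
}

parse_terms <- function(txt) {
  txt <- trimws(txt)
  if (txt == ".") return(character())
  raw <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
  out <- character()
  for (tm in raw) {
    tm <- gsub("\\s+", " ", tm)
    norm <- gsub(" ", "", tm)
    norm <- sub("\\^2$", "2", norm)
    if (grepl("\\*", norm)) {
      ab <- strsplit(norm, "*", fixed = TRUE)[[1]]
      out <- c(out, ab, paste(sort(ab), collapse = ":"))
    } else if (grepl(":", norm)) {
      ab <- strsplit(norm, ":", fixed = TRUE)[[1]]
      out <- c(out, paste(sort(ab), collapse = ":"))
    } else {
      out <- c(out, norm)
    }
  }
  unique(out)
}

#' The nine-model candidate set
#'
#' The growth-rate model set compared by WAIC: a climate-only null through a
#' global model with quadratic density and climate terms and a
#' climate-by-density interaction. All models share the four-covariate
#' detection structure (wind, noise, date, time); all but the last put
#' climate on initial abundance.
#'
#' @return A named list of nine [nmix_spec()] objects.
#' @export
build_model_set <- function() {
  specs <- list(
    nmix_spec(lambda_terms = c("climate", "treatment", "density")),
    nmix_spec(lambda_terms = c("climate", "treatment", "density", "density2")),
    nmix_spec(lambda_terms = c("climate", "density", "climate:density")),
    nmix_spec(lambda_terms = c("climate", "density")),
    nmix_spec(lambda_terms = LAMBDA_TERMS, label = "Global"),
    nmix_spec(lambda_terms = character()),
    nmix_spec(lambda_terms = c("climate", "treatment")),
    nmix_spec(lambda_terms = "climate"),
    nmix_spec(psi_terms = character(), lambda_terms = character())
  )
  names(specs) <- vapply(specs, `[[`, "", "label")
  specs
}

`%||%` <- function(a, b) if (is.null(a)) b else a
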