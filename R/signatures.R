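#' Fit non-negative signature exposures to a catalog
#'
#' Least-squares refit of catalog channel frequencies against a fixed
#' signature matrix under non-negativity (Lawson-Hanson NNLS). Exposures
#' are returned both as raw weights and as fractions summing to 1.
#'
#' @param catalog Named length-96 count vector (see [build_96_catalog()]).
#' @param signature_matrix 96 x K signature matrix with named columns.
#' @return List with `weights`, `fractions` (named numeric vectors),
#'   `residual` (Euclidean norm of the frequency residual) and `zero`
#'   (TRUE when the catalog was empty, in which case exposures are zero).
#' @export
fit_signature_exposures <- function(catalog, signature_matrix) {
  validate_signature_matrix(signature_matrix)
  stopifnot(length(catalog) == 96, all(catalog >= 0))
  K <- ncol(signature_matrix)
  if (sum(catalog) == 0) {
    z <- setNames(numeric(K), colnames(signature_matrix))
    return(list(weights = z, fractions = z, residual = 0, zero = TRUE))
  }
  f <- as.numeric(catalog) / sum(catalog)
  fit <- pracma::lsqnonneg(signature_matrix, f)
  w <- setNames(pmax(fit$x, 0), colnames(signature_matrix))
  fr <- if (sum(w) > 0) w / sum(w) else w
  list(weights = w, fractions = fr,
       residual = sqrt(sum((signature_matrix %*% w - f)^2)), zero = FALSE)
}

.multinom_ll <- function(catalog, probs, floor = 1e-12) {
  p <- pmax(probs / sum(probs), floor)
  sum(catalog * log(p))
}

.sig3_llr <- function(catalog, signature_matrix, sig3 = "Signature 3") {
  keep <- colnames(signature_matrix) != sig3
  full <- fit_signature_exposures(catalog, signature_matrix)
  red <- fit_signature_exposures(catalog, signature_matrix[, keep, drop = FALSE])
  pf <- as.vector(signature_matrix %*% full$weights)
  pr <- as.vector(signature_matrix[, keep, drop = FALSE] %*% red$weights)
  list(score = .multinom_ll(catalog, pf) - .multinom_ll(catalog, pr),
       exposure = unname(full$fractions[sig3]))
}

#' Calibrate the Signature-3 presence threshold
#'
#' The Signature-3 caller is a likelihood-ratio test: the multinomial
#' log-likelihood of the NNLS refit with the full signature set minus the
#' refit without the Signature 3 column. Its null distribution depends on
#' the signature set and the mutation count, so the decision threshold is
#' calibrated by simulation: catalogs are drawn from random
#' (Dirichlet-weighted) mixtures of the non-Signature-3 columns and the
#' threshold is set at the (1 - fpr) tail of the resulting null scores so
#' the false-positive rate on null tumors is at most `fpr`.
#'
#' @param signature_matrix 96 x K signature matrix.
#' @param n_snvs Mutation count per simulated null catalog (exome-scale
#'   default 50).
#' @param n_null Number of null catalogs.
#' @param fpr Target false-positive rate.
#' @param min_snvs Catalogs smaller than this are not called (no-call).
#' @param sig3 Column name of the HRD signature.
#' @param seed Integer seed for the null simulation.
#' @return Object of class `sig3_calibration`: list with `threshold`,
#'   `null_scores`, and the calibration settings.
#' @export
calibrate_sig3 <- function(signature_matrix = synthetic_signatures(),
                           n_snvs = 50, n_null = 1000, fpr = 0.05,
                           min_snvs = 5, sig3 = "Signature 3", seed = 1L) {
  validate_signature_matrix(signature_matrix)
  stopifnot(sig3 %in% colnames(signature_matrix), n_null >= 20)
  other <- setdiff(colnames(signature_matrix), sig3)
  rng <- local_rng(seed)
  scores <- vapply(seq_len(n_null), function(i) {
    w <- stats::rgamma(length(other), 1)
    e <- setNames(numeric(ncol(signature_matrix)), colnames(signature_matrix))
    e[other] <- w / sum(w)
    cat_ <- simulate_catalog(e, n_snvs, signature_matrix, seed = NULL)
    .sig3_llr(cat_, signature_matrix, sig3)$score
  }, numeric(1))
  restore_rng(rng)
  k <- max(1L, floor(fpr * n_null))
  structure(
    list(threshold = sort(scores, decreasing = TRUE)[k],
         null_scores = scores, n_snvs = n_snvs, n_null = n_null,
         fpr = fpr, min_snvs = min_snvs, sig3 = sig3, seed = seed),
    class = "sig3_calibration"
  )
}

#' Call Signature-3 presence in a tumor catalog
#'
#' @param catalog Length-96 count vector.
#' @param signature_matrix 96 x K signature matrix.
#' @param calibration A `sig3_calibration` (see [calibrate_sig3()]).
#' @return List with `sig3_present` (logical, NA = no-call on
#'   low-mutation-count catalogs), `sig3_score` (log-likelihood ratio),
#'   `sig3_exposure` (NNLS fraction) and `low_mutation_count` flag.
#' @export
call_sig3 <- function(catalog, signature_matrix = synthetic_signatures(),
                      calibration) {
  stopifnot(inherits(calibration, "sig3_calibration"))
  if (sum(catalog) < calibration$min_snvs) {
    return(list(sig3_present = NA, sig3_score = NA_real_,
                sig3_exposure = NA_real_, low_mutation_count = TRUE))
  }
  r <- .sig3_llr(catalog, signature_matrix, calibration$sig3)
  list(sig3_present = r$score > calibration$threshold,
       sig3_score = r$score, sig3_exposure = r$exposure,
       low_mutation_count = FALSE)
}
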