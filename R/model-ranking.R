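# AICc model ranking with Akaike weights.

#' Rank CJS models by AICc
#'
#' Builds the usual model-selection table: models sorted by ascending AICc,
#' the difference to the top model (`delta`) and Akaike weights
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)`. Ties in AICc break
#' by fewer parameters, then by name.
#'
#' @param fits a list of `cjs_fit` objects fitted to the same data, or a
#'   named numeric vector of AICc values (for table arithmetic on published
#'   values).
#' @param k optional integer vector of parameter counts when `fits` is
#'   numeric.
#' @return A data frame of class `cjs_ranking` with columns `model`, `k`,
#'   `aicc`, `delta`, `weight`.
#' @examples
#' aicc <- c(m1 = 619.6521, m2 = 630.4739, m3 = 633.4523)
#' rank_models(aicc)
#' @export
rank_models <- function(fits, k = NULL) {
  if (is.numeric(fits)) {
    aicc <- as.numeric(fits)
    nm <- names(fits)
    if (is.null(nm)) nm <- sprintf("model%d", seq_along(aicc))
    kk <- if (is.null(k)) rep(NA_integer_, length(aicc)) else as.integer(k)
  } else {
    if (!length(fits) || !all(vapply(fits, inherits, TRUE, "cjs_fit"))) {
      stop("fits must be cjs_fit objects or a numeric AICc vector")
    }
    sig <- vapply(fits, function(f) {
      paste(dim(f$data$ch), collapse = "x")
    }, "")
    if (length(unique(sig)) != 1L ||
        length(unique(vapply(fits, function(f) sum(f$data$ch), 0))) != 1L) {
      stop("all models must be fitted to the same data")
    }
    aicc <- vapply(fits, function(f) f$aicc, 0)
    nm <- vapply(fits, function(f) f$model, "")
    kk <- vapply(fits, function(f) f$k, 0L)
  }
  if (!length(aicc)) stop("no models to rank")
  delta <- aicc - min(aicc)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  out <- data.frame(model = nm, k = kk, aicc = aicc, delta = delta,
                    weight = w, stringsAsFactors = FALSE)
  ord <- order(out$aicc, out$k, out$model)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cjs_ranking", "data.frame")
  out
}

#' @export
print.cjs_ranking <- function(x, digits = 4, ...) {
  cat("Model ranking by AICc (", nrow(x), " models)\n", sep = "")
  df <- as.data.frame(x)
  df$aicc <- round(df$aicc, digits)
  df$delta <- round(df$delta, digits)
  df$weight <- signif(df$weight, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Akaike weights from information-criterion values
#'
#' @param ic numeric vector of AICc (or AIC) values.
#' @return numeric vector of weights summing to 1.
#' @export
akaike_weights <- function(ic) {
  if (!length(ic)) stop("empty input")
  d <- ic - min(ic)
  w <- exp(-d / 2)
  w / sum(w)
}
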