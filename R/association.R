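#' Build the design table for a class-attribute association test
#'
#' One row per node assigned a balance class and carrying an attribute
#' estimate: the three-level outcome (`-1` not have, `0` inconclusive, `+1`
#' have, with `0` as the reference level) and `K - 1` class indicator columns,
#' the reference class being omitted (dummy coding).
#'
#' @param partition a `balance_trial` from [optimize_partition()] (its first
#'   optimal partition is used) or a named node -> class vector.
#' @param estimates an `attribute_estimate` from [ascribe_all()].
#' @param attribute attribute id to model.
#' @param reference_class class index taken as the baseline; defaults to the
#'   largest class.
#' @return data frame with columns `outcome` (factor, reference level `"0"`)
#'   and `class_<c>` indicators; attributes `reference_class`, `attribute`,
#'   `n_excluded` (nodes lacking an estimate) and `degenerate` (all-zero
#'   design).
#' @export
build_design <- function(partition, estimates, attribute, reference_class = NULL) {
  if (inherits(partition, "balance_trial")) partition <- partition$partitions[[1]]
  if (is.null(names(partition))) stopf("partition must be a named node -> class vector")
  stopifnot(inherits(estimates, "attribute_estimate"))
  if (!attribute %in% colnames(estimates$q_tilde))
    stopf("unknown attribute '%s'", attribute)

  nodes <- names(partition)
  known <- nodes %in% rownames(estimates$q_tilde)
  n_excluded <- sum(!known)
  if (n_excluded) message(sprintf("%d node(s) lack an attribute estimate and are excluded",
                                  n_excluded))
  nodes <- nodes[known]
  cls <- as.integer(partition[nodes])
  outcome <- factor(estimates$q_tilde[nodes, attribute], levels = c("0", "-1", "1"))

  if (is.null(reference_class)) {
    sizes <- table(cls)
    reference_class <- as.integer(names(sizes)[which.max(sizes)])
  }
  classes <- sort(unique(cls))
  if (!reference_class %in% classes) stopf("reference class %d not present", reference_class)
  others <- setdiff(classes, reference_class)

  design <- data.frame(outcome = outcome, row.names = nodes)
  for (c in others) design[[paste0("class_", c)]] <- as.integer(cls == c)
  attr(design, "reference_class") <- reference_class
  attr(design, "attribute") <- attribute
  attr(design, "n_excluded") <- n_excluded
  attr(design, "degenerate") <- length(others) == 0L ||
    all(as.matrix(design[, -1, drop = FALSE]) == 0L)
  design
}

#' Fit the multinomial logistic association model
#'
#' Maximum-likelihood multinomial logit of the three-level attribute outcome
#' on the class indicators, with the inconclusive outcome (`"0"`) as the
#' reference category. Plain ML with an iteration cap; no penalization.
#' Quasi-separation (an empty class-by-outcome cell) is flagged rather than
#' suppressed, since it produces the familiar huge coefficient/standard-error
#' pairs.
#'
#' @param design a design table from [build_design()].
#' @return an object of class `association_model`: `coefficients` and
#'   `std_errors` (matrices, one row per non-reference outcome), `aic`,
#'   `converged`, `separation`, `fitted` (per-row outcome probabilities),
#'   `reference_class`, `attribute`, and the underlying `nnet::multinom` fit.
#' @export
fit_multinomial <- function(design) {
  outcome <- droplevels(design$outcome)
  if (nlevels(outcome) < 2L)
    stopf("degenerate outcome: only level '%s' present", levels(outcome)[1])
  design$outcome <- outcome
  preds <- setdiff(names(design), "outcome")

  cls_cell <- interaction(design[, preds, drop = FALSE], drop = TRUE)
  separation <- any(table(cls_cell, outcome) == 0L)

  fml <- stats::as.formula(paste("outcome ~",
                                 if (length(preds)) paste(preds, collapse = " + ") else "1"))
  fit <- nnet::multinom(fml, data = design, trace = FALSE, Hess = TRUE, maxit = 500)
  sm <- tryCatch(summary(fit), error = function(e) NULL)

  coefs <- stats::coef(fit)
  if (is.null(dim(coefs))) {
    coefs <- matrix(coefs, nrow = 1,
                    dimnames = list(setdiff(levels(outcome), levels(outcome)[1]),
                                    names(coefs)))
  }
  ses <- if (!is.null(sm)) {
    se <- sm$standard.errors
    if (is.null(dim(se))) matrix(se, nrow = 1, dimnames = dimnames(coefs)) else se
  } else coefs * NA_real_

  structure(list(coefficients = coefs, std_errors = ses,
                 aic = stats::AIC(fit),
                 converged = fit$convergence == 0L,
                 separation = separation,
                 fitted = stats::fitted(fit),
                 reference_class = attr(design, "reference_class"),
                 attribute = attr(design, "attribute"),
                 fit = fit),
            class = "association_model")
}

#' @export
print.association_model <- function(x, ...) {
  cat(sprintf("<association_model> attribute %s, reference class %s, AIC = %.3f%s%s\n",
              x$attribute %||% "?", x$reference_class %||% "?", x$aic,
              if (!x$converged) " [not converged]" else "",
              if (x$separation) " [quasi-separation]" else ""))
  cat("Coefficients:\n"); print(round(x$coefficients, 3))
  cat("Std. errors:\n"); print(round(x$std_errors, 3))
  invisible(x)
}
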