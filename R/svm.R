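#' Radial-basis kernel matrix
#'
#' `K(x, y) = exp(-gamma * ||x - y||^2)`, the SVM-light parameterisation, so
#' published gamma values can be used directly.
#'
#' @param x,y Numeric matrices (rows are observations); `y` defaults to `x`.
#' @param gamma Positive kernel width parameter.
#' @return `nrow(x)` x `nrow(y)` kernel matrix.
#' @export
rbf_kernel <- function(x, y = x, gamma) {
  if (gamma <= 0) stop_pgact("'gamma' must be positive")
  x <- as.matrix(x); y <- as.matrix(y)
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

#' Train a binary soft-margin RBF support vector machine
#'
#' Solves the usual SVM dual with a sequential-minimal-optimisation solver
#' (maximal-violating-pair working-set selection, KKT tolerance `tol`).  The
#' solver is deterministic: identical inputs give identical models.
#'
#' @param x Feature matrix (rows are examples) as from [feature_matrix()].
#' @param y Labels, coercible to -1/+1 (numeric signs or logical).
#' @param gamma RBF width (must be > 0).
#' @param cost Soft-margin trade-off C (must be > 0).
#' @param tol KKT stopping tolerance (default 1e-3, the LIBSVM default).
#' @param max_iter Cap on SMO pair updates.
#' @return An object of class `pga_svm` holding the support vectors, their
#'   coefficients `alpha_i * y_i`, the offset `b`, and the hyperparameters.
#'   Decision values are `sum_i coef_i K(sv_i, x) + b`.
#' @export
svm_train <- function(x, y, gamma, cost, tol = 1e-3, max_iter = 1000000L) {
  x <- as.matrix(x)
  y <- as.integer(sign(as.numeric(y)))
  if (any(y == 0)) stop_pgact("labels must be nonzero (+1/-1)")
  if (length(y) != nrow(x)) stop_pgact("one label per row required")
  if (length(unique(y)) < 2)
    stop_pgact("training needs at least one example of each class")
  if (gamma <= 0 || cost <= 0) stop_pgact("'gamma' and 'cost' must be positive")
  K <- rbf_kernel(x, gamma = gamma)
  sol <- .smo_solve(K, y, as.numeric(cost), tol, as.integer(max_iter))
  if (!sol$converged)
    warning("SMO did not reach tolerance ", tol, " within ", max_iter,
            " iterations", call. = FALSE)
  sv <- which(sol$alpha > 1e-12)
  structure(list(sv = x[sv, , drop = FALSE],
                 coef = sol$alpha[sv] * y[sv],
                 b = -sol$rho,
                 gamma = gamma, cost = cost,
                 n_features = ncol(x),
                 iterations = sol$iterations),
            class = "pga_svm")
}

#' Decision values of a trained SVM
#'
#' @param model A `pga_svm`.
#' @param x Feature matrix of new observations (same encoding and width).
#' @return Numeric vector of signed decision values (positive class above 0).
#' @export
svm_decision <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model$n_features)
    stop_pgact("feature dimension mismatch: model expects ", model$n_features,
               ", got ", ncol(x))
  as.vector(crossprod(rbf_kernel(model$sv, x, gamma = model$gamma),
                      model$coef)) + model$b
}

#' @export
print.pga_svm <- function(x, ...) {
  cat("RBF SVM: gamma =", x$gamma, " C =", x$cost,
      " support vectors =", nrow(x$sv),
      " (", x$n_features, "features )\n")
  invisible(x)
}

# --- plain-text serialisation -------------------------------------------------
#
# Doubles are written with "%.17g", which round-trips IEEE-754 exactly, so a
# saved and reloaded model reproduces decision values bit for bit.

svm_save <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("gamma\t%.17g", model$gamma),
               sprintf("cost\t%.17g", model$cost),
               sprintf("b\t%.17g", model$b),
               sprintf("n_features\t%d", model$n_features),
               sprintf("n_sv\t%d", nrow(model$sv))), con)
  writeLines(paste0("coef\t",
                    paste(sprintf("%.17g", model$coef), collapse = "\t")), con)
  for (i in seq_len(nrow(model$sv)))
    writeLines(paste0("sv\t",
                      paste(sprintf("%.17g", model$sv[i, ]), collapse = "\t")),
               con)
  invisible(path)
}

svm_load <- function(path) {
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  key <- vapply(fields, `[[`, "", 1)
  val <- function(k) fields[[match(k, key)]][-1]
  nf <- as.integer(val("n_features"))
  svl <- fields[key == "sv"]
  sv <- do.call(rbind, lapply(svl, function(f) as.numeric(f[-1])))
  if (is.null(sv)) sv <- matrix(numeric(0), 0, nf)
  structure(list(sv = sv,
                 coef = as.numeric(val("coef")),
                 b = as.numeric(val("b")),
                 gamma = as.numeric(val("gamma")),
                 cost = as.numeric(val("cost")),
                 n_features = nf,
                 iterations = NA_integer_),
            class = "pga_svm")
}
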