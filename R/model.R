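#' Published default SVM hyperparameters
#'
#' The RBF width gamma and soft-margin cost C optimised for each feature
#' encoding, for the level-1 activator/non-activator model and for the four
#' one-vs-rest subfamily models.  These are the shipped defaults; pass a
#' modified copy to [pga_fit()] to override.
#'
#' @param method Feature encoding: `"AC"`, `"DC"`, `"PSSM"` or `"HYBRID"`.
#' @return Named list of `c(gamma, cost)` pairs with elements `level1`,
#'   `SAK`, `SK`, `tPA`, `UK`.
#' @export
#' @examples
#' pga_params("AC")$level1  # gamma 25, cost 450
pga_params <- function(method = c("AC", "DC", "PSSM", "HYBRID")) {
  method <- match.arg(method)
  tab <- list(
    AC     = list(level1 = c(gamma = 25, cost = 450),
                  SAK = c(gamma = 3, cost = 300),
                  SK  = c(gamma = 3, cost = 275),
                  tPA = c(gamma = 50, cost = 100),
                  UK  = c(gamma = 3, cost = 300)),
    DC     = list(level1 = c(gamma = 3, cost = 375),
                  SAK = c(gamma = 3, cost = 75),
                  SK  = c(gamma = 10, cost = 25),
                  tPA = c(gamma = 15, cost = 450),
                  UK  = c(gamma = 15, cost = 500)),
    PSSM   = list(level1 = c(gamma = 3, cost = 400),
                  SAK = c(gamma = 1, cost = 300),
                  SK  = c(gamma = 1, cost = 400),
                  tPA = c(gamma = 4, cost = 200),
                  UK  = c(gamma = 5, cost = 9)),
    HYBRID = list(level1 = c(gamma = 1, cost = 450),
                  SAK = c(gamma = 1, cost = 150),
                  SK  = c(gamma = 1, cost = 250),
                  tPA = c(gamma = 10, cost = 450),
                  UK  = c(gamma = 1, cost = 450)))
  tab[[method]]
}

#' Fit the hierarchical plasminogen-activator classifier suite
#'
#' Trains up to five RBF SVMs on a labelled dataset: a level-1 model with all
#' activator subfamilies (SAK, SK, tPA, UK) as positives against the `NEG`
#' class, and four one-vs-rest subfamily models in which one subfamily is
#' positive and the other three subfamilies are the negatives (`NEG` is
#' excluded at level 2 — the level-1 gate handles non-activators).  A missing
#' subfamily only drops its model, with a warning.
#'
#' @param data A labelled `pga_dataset` containing `NEG` and at least one
#'   activator subfamily.
#' @param method Feature encoding: `"AC"`, `"DC"`, `"PSSM"` or `"HYBRID"`.
#' @param params Hyperparameter list as from [pga_params()] (the default).
#' @param pssm,seed Passed to [feature_matrix()] for PSSM encodings.
#' @param tol SMO stopping tolerance.
#' @return An object of class `pga_fit` with `print`, `summary` and
#'   `predict` methods.
#' @seealso [predict.pga_fit()], [cross_validate()], [save_model()]
#' @export
#' @examples
#' bench <- default_benchmark(seed = 1, scale = 0.1)
#' fit <- pga_fit(bench, method = "AC")
#' fit
pga_fit <- function(data, method = c("AC", "DC", "PSSM", "HYBRID"),
                    params = NULL, pssm = "mock", seed = 1, tol = 1e-3) {
  method <- match.arg(method)
  if (is.null(params)) params <- pga_params(method)
  if (is.null(data$label)) stop_pgact("'data' must carry a 'label' column")
  if (!any(data$label == "NEG"))
    stop_pgact("training data must contain NEG examples")
  if (!any(data$label %in% PGA_CLASSES))
    stop_pgact("training data must contain at least one activator subfamily")

  feats <- feature_matrix(data, method, pssm = pssm, seed = seed)
  lab <- data$label

  p <- function(name) {
    v <- params[[name]]
    if (is.null(v) || length(v) < 2)
      stop_pgact("params must supply c(gamma, cost) for '", name, "'")
    v
  }

  models <- list()
  v <- p("level1")
  models$level1 <- svm_train(feats, ifelse(lab == "NEG", -1, 1),
                             gamma = v[[1]], cost = v[[2]], tol = tol)

  pos_idx <- which(lab %in% PGA_CLASSES)
  for (cls in PGA_CLASSES) {
    if (!any(lab == cls)) {
      warning("subfamily '", cls, "' absent from training data; ",
              "its model is skipped", call. = FALSE)
      next
    }
    if (!any(lab[pos_idx] != cls)) {
      warning("subfamily '", cls, "' is the only activator class present; ",
              "one-vs-rest model needs other subfamilies and is skipped",
              call. = FALSE)
      next
    }
    v <- p(cls)
    models[[cls]] <- svm_train(feats[pos_idx, , drop = FALSE],
                               ifelse(lab[pos_idx] == cls, 1, -1),
                               gamma = v[[1]], cost = v[[2]], tol = tol)
  }

  structure(list(models = models,
                 method = method,
                 params = params,
                 alphabet = paste(AA20, collapse = ""),
                 n_features = ncol(feats),
                 class_counts = table(factor(lab, levels = ALL_LABELS)),
                 call = match.call()),
            class = "pga_fit")
}

#' Two-stage prediction of plasminogen activators
#'
#' Level 1 scores each sequence with the activator/non-activator model and
#' calls `PG` when the decision value is at least `threshold` (default 0, the
#' SVM margin).  For sequences called `PG`, all four subfamily models are
#' scored and the call is the argmax, ties broken in the fixed order
#' SAK < SK < tPA < UK.  Sequences called `NON_PG` get no subfamily scores.
#'
#' @param object A `pga_fit`.
#' @param newdata A `pga_dataset`, a data frame with `id`/`residues`, or a
#'   character vector of residue strings.
#' @param threshold Level-1 decision threshold; raising it can only turn
#'   `PG` calls into `NON_PG`.
#' @param pssm,seed Passed to [feature_matrix()] for PSSM encodings.
#' @param ... Unused.
#' @return A data frame of class `pga_prediction`: `id`, `level1_score`,
#'   `level1_call` (`PG`/`NON_PG`), `score_SAK` ... `score_UK` (NA for
#'   `NON_PG`), `subclass_call` (NA for `NON_PG`).
#' @export
predict.pga_fit <- function(object, newdata, threshold = 0,
                            pssm = "mock", seed = 1, ...) {
  if (is.character(newdata))
    newdata <- pga_dataset(paste0("seq", seq_along(newdata)), newdata,
                           validate = NULL)
  feats <- feature_matrix(newdata, object$method, pssm = pssm, seed = seed)
  if (ncol(feats) != object$n_features)
    stop_pgact("feature dimension mismatch with fitted model")

  l1 <- svm_decision(object$models$level1, feats)
  call1 <- ifelse(l1 >= threshold, "PG", "NON_PG")

  sub <- matrix(NA_real_, nrow(feats), length(PGA_CLASSES),
                dimnames = list(NULL, PGA_CLASSES))
  sub_call <- rep(NA_character_, nrow(feats))
  pg <- which(call1 == "PG")
  avail <- intersect(PGA_CLASSES, names(object$models))
  if (length(pg) > 0 && length(avail) > 0) {
    for (cls in avail)
      sub[pg, cls] <- svm_decision(object$models[[cls]],
                                   feats[pg, , drop = FALSE])
    # which.max on the fixed column order implements the documented tie-break
    sub_call[pg] <- avail[apply(sub[pg, avail, drop = FALSE], 1, which.max)]
  }

  out <- data.frame(id = newdata$id,
                    level1_score = l1,
                    level1_call = call1,
                    score_SAK = sub[, "SAK"], score_SK = sub[, "SK"],
                    score_tPA = sub[, "tPA"], score_UK = sub[, "UK"],
                    subclass_call = sub_call,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  class(out) <- c("pga_prediction", "data.frame")
  out
}

#' @export
print.pga_fit <- function(x, ...) {
  cat("Hierarchical plasminogen-activator SVM suite\n")
  cat("  feature encoding:", x$method, "(", x$n_features, "dimensions )\n")
  cat("  training classes:",
      paste(names(x$class_counts), as.integer(x$class_counts),
            sep = "=", collapse = " "), "\n")
  cat("  models:", paste(names(x$models), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.pga_fit <- function(object, ...) {
  rows <- lapply(names(object$models), function(nm) {
    m <- object$models[[nm]]
    data.frame(model = nm, gamma = m$gamma, cost = m$cost,
               support_vectors = nrow(m$sv), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(list(method = object$method, table = out,
                 class_counts = object$class_counts),
            class = "summary.pga_fit")
}

#' @export
print.summary.pga_fit <- function(x, ...) {
  cat("pga_fit (", x$method, "features )\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Save or load a fitted model bundle
#'
#' The bundle is a directory holding one plain-text file per SVM plus a JSON
#' manifest recording the feature method, hyperparameters and the residue
#' alphabet (an ordering checksum).  Loading refuses a bundle whose alphabet
#' does not match the running package, and a reloaded model reproduces
#' decision values bit for bit.
#'
#' @param object A `pga_fit`.
#' @param dir Bundle directory (created if needed).
#' @return `save_model`: `dir`, invisibly.  `load_model`: the `pga_fit`.
#' @export
save_model <- function(object, dir) {
  if (!inherits(object, "pga_fit")) stop_pgact("'object' must be a pga_fit")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "pgact",
                   method = object$method,
                   alphabet = object$alphabet,
                   n_features = object$n_features,
                   params = lapply(object$params, as.list),
                   models = names(object$models),
                   class_counts = as.list(object$class_counts))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(object$models))
    svm_save(object$models[[nm]], file.path(dir, paste0(nm, ".svm")))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop_pgact("not a model bundle (no manifest): ", dir)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  if (!identical(mf$alphabet, paste(AA20, collapse = "")))
    stop_pgact("model bundle was built with a different residue ordering; ",
               "refusing to load")
  models <- lapply(mf$models, function(nm) svm_load(file.path(dir,
                                                              paste0(nm, ".svm"))))
  names(models) <- mf$models
  cc <- unlist(mf$class_counts)
  structure(list(models = models,
                 method = mf$method,
                 params = lapply(mf$params, unlist),
                 alphabet = mf$alphabet,
                 n_features = mf$n_features,
                 class_counts = cc,
                 call = NULL),
            class = "pga_fit")
}
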