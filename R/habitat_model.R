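#' Case-control habitat-selection GAMs
#'
#' The use/pseudo-absence label is modelled with binomial GAMs whose smooth
#' terms are cubic regression splines with shrinkage (`bs = "cs"`), initially
#' limited to 3 knots to avoid overfitting and raised (to at most 5) only when
#' a residual check flags poor fit. Covariates enter by forward stepwise
#' selection ordered by single-covariate cross-validated AUC; model
#' performance is assessed by leave-one-colony-out cross-validated ROC
#' (random-split cross-validation when only one colony was tracked).
#'
#' @name habitat_model
NULL

#' Fit a binomial GAM with shrinkage splines
#'
#' @param table Case-control data.frame with a 0/1 `label` column and
#'   standardized covariate columns (`<name>_std`).
#' @param terms Character vector of covariate names (standardized columns are
#'   used); `character(0)` fits the intercept-only model.
#' @param knots Named integer vector of per-term basis dimensions; unnamed
#'   terms default to `default_knots`.
#' @param default_knots Basis dimension when not given per term (default 3).
#' @param tensor Optional length-2 character: fit these two covariates as a
#'   single tensor-product smooth instead of two marginal smooths.
#' @param engine `"auto"` (bam with discretized covariates above 8000 rows,
#'   gam otherwise), `"gam"`, or `"bam"`. Smoothing parameters are selected by
#'   (f)REML in either engine.
#' @return Object of class `cpf_gam`: the mgcv fit plus term bookkeeping and
#'   per-term effective degrees of freedom.
#' @export
fit_binomial_gam <- function(table, terms, knots = integer(0), default_knots = 3L,
                             tensor = NULL, engine = c("auto", "gam", "bam")) {
  engine <- match.arg(engine)
  stopifnot(all(c(0, 1) %in% table$label))
  kn <- stats::setNames(rep(default_knots, length(terms)), terms)
  kn[names(knots)[names(knots) %in% terms]] <- knots[names(knots) %in% terms]
  pieces <- character(0)
  if (!is.null(tensor)) {
    stopifnot(length(tensor) == 2, all(tensor %in% terms))
    pieces <- sprintf("te(%s_std, %s_std, bs = 'cs', k = %d)",
                      tensor[1], tensor[2], max(kn[tensor]))
    terms_marginal <- setdiff(terms, tensor)
  } else {
    terms_marginal <- terms
  }
  pieces <- c(pieces, sprintf("s(%s_std, bs = 'cs', k = %d)", terms_marginal,
                              kn[terms_marginal]))
  rhs <- if (length(pieces)) paste(pieces, collapse = " + ") else "1"
  form <- stats::as.formula(paste("label ~", rhs))
  use_bam <- engine == "bam" || (engine == "auto" && nrow(table) > 8000)
  fit <- tryCatch({
    if (use_bam && length(pieces)) {
      mgcv::bam(form, family = stats::binomial(), data = table,
                method = "fREML", discrete = TRUE)
    } else {
      mgcv::gam(form, family = stats::binomial(), data = table, method = "REML")
    }
  }, error = function(e) {
    stop("binomial GAM failed to converge for terms [",
         paste(terms, collapse = ", "), "]: ", conditionMessage(e))
  })
  if (any(abs(stats::coef(fit)) > 50)) {
    warning("very large coefficients: possible complete separation")
  }
  edf <- if (length(fit$smooth)) {
    vapply(fit$smooth, function(sm) sum(fit$edf[sm$first.para:sm$last.para]),
           numeric(1))
  } else numeric(0)
  names(edf) <- vapply(fit$smooth, function(sm) sm$label, character(1))
  structure(list(fit = fit, terms = terms, knots = kn, tensor = tensor,
                 edf = edf, n = nrow(table),
                 engine = if (use_bam && length(pieces)) "bam/fREML" else "gam/REML"),
            class = "cpf_gam")
}

#' @export
print.cpf_gam <- function(x, ...) {
  cat(sprintf("<cpf_gam> %s; terms: %s; n = %d\n", x$engine,
              if (length(x$terms)) paste(x$terms, collapse = " + ") else "(intercept only)",
              x$n))
  invisible(x)
}

#' Predict on the linear-predictor or response scale
#'
#' @param object A `cpf_gam`.
#' @param newdata data.frame with the needed `_std` columns.
#' @param type `"link"` or `"response"`.
#' @param ... Unused.
#' @export
predict.cpf_gam <- function(object, newdata, type = "link", ...) {
  as.numeric(mgcv::predict.gam(object$fit, newdata = newdata, type = type))
}

#' ROC metrics: AUC, sensitivity and specificity
#'
#' AUC uses the rank (Mann-Whitney) formulation, counting ties as 1/2.
#' Sensitivity (correctly predicted presences) and specificity (correctly
#' predicted absences) are evaluated at the threshold maximizing Youden's J
#' (sensitivity + specificity - 1), predicting presence when
#' `score >= threshold`.
#'
#' @param scores Numeric scores (higher = more presence-like).
#' @param labels 0/1 labels; both classes must be present.
#' @return List with `auc`, `sensitivity`, `specificity`, `threshold`.
#' @export
roc_metrics <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute ROC metrics")
  r <- rank(scores)   # midranks handle ties as 1/2
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  lab_sorted <- labels[ord]; sc_sorted <- scores[ord]
  tp <- cumsum(lab_sorted); fp <- cumsum(1 - lab_sorted)
  # evaluate only at the last index of each tied score block
  last <- c(sc_sorted[-1] != sc_sorted[-length(sc_sorted)], TRUE)
  sens <- tp[last] / n1
  spec <- 1 - fp[last] / n0
  best <- which.max(sens + spec)
  list(auc = auc, sensitivity = sens[best], specificity = spec[best],
       threshold = sc_sorted[last][best])
}

#' Cross-validation fold schemes
#'
#' `"colony"` mode gives leave-one-colony-out folds (k = number of tracked
#' colonies, each colony the test set exactly once); `"random"` mode gives a
#' single random train/test split for groups with one tracked colony.
#'
#' @param table Case-control data.frame with `colony_id`.
#' @param mode `"colony"` or `"random"`.
#' @param test_fraction Test proportion for random mode (default 0.25).
#' @param seed Seed for random mode.
#' @return List of class `fold_scheme`: `test_sets` (list of row-index
#'   vectors) and `mode`.
#' @export
fold_scheme <- function(table, mode = c("colony", "random"),
                        test_fraction = 0.25, seed = 1) {
  mode <- match.arg(mode)
  if (mode == "colony") {
    ids <- unique(table$colony_id)
    if (length(ids) < 2) stop("colony folds need >= 2 tracked colonies; use mode = 'random'")
    sets <- lapply(ids, function(cid) which(table$colony_id == cid))
    names(sets) <- ids
  } else {
    sets <- with_seed(seed, {
      n_test <- max(1L, round(nrow(table) * test_fraction))
      list(random_split = sample.int(nrow(table), n_test))
    })
  }
  structure(list(test_sets = sets, mode = mode), class = "fold_scheme")
}

#' Cross-validated ROC evaluation of a term set
#'
#' Per fold: fit on the training rows, score the test rows, compute
#' [roc_metrics()]. Folds whose test set lacks a class are skipped with a
#' warning. Reports mean and SD over evaluated folds.
#'
#' @param table Case-control data.frame.
#' @param terms Covariate names.
#' @param folds A [fold_scheme()].
#' @inheritParams fit_binomial_gam
#' @return List with `auc`, `sensitivity`, `specificity` (each `c(mean, sd)`),
#'   `per_fold` data.frame, `n_folds_used`.
#' @export
cv_evaluate <- function(table, terms, folds, knots = integer(0),
                        default_knots = 3L, tensor = NULL,
                        engine = c("auto", "gam", "bam")) {
  engine <- match.arg(engine)
  rows <- lapply(seq_along(folds$test_sets), function(i) {
    test_idx <- folds$test_sets[[i]]
    test <- table[test_idx, , drop = FALSE]
    train <- table[-test_idx, , drop = FALSE]
    if (length(unique(test$label)) < 2 || length(unique(train$label)) < 2) {
      warning("fold '", names(folds$test_sets)[i] %||% i,
              "' lacks a class and was skipped")
      return(NULL)
    }
    m <- fit_binomial_gam(train, terms, knots = knots,
                          default_knots = default_knots, tensor = tensor,
                          engine = engine)
    sc <- predict.cpf_gam(m, test, type = "response")
    rm <- roc_metrics(sc, test$label)
    data.frame(fold = names(folds$test_sets)[i] %||% as.character(i),
               auc = rm$auc, sensitivity = rm$sensitivity,
               specificity = rm$specificity, stringsAsFactors = FALSE)
  })
  per_fold <- do.call(rbind, rows)
  if (is.null(per_fold) || nrow(per_fold) == 0) stop("no evaluable folds")
  msd <- function(v) c(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0)
  list(auc = msd(per_fold$auc), sensitivity = msd(per_fold$sensitivity),
       specificity = msd(per_fold$specificity), per_fold = per_fold,
       n_folds_used = nrow(per_fold))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Wald-Wolfowitz runs test p-value on the signs of residuals ordered by a
# covariate; small p flags structured (poorly fitted) residuals
runs_test_p <- function(res, order_by) {
  s <- sign(res[order(order_by)])
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0)
  if (n1 == 0 || n2 == 0) return(1)
  runs <- 1 + sum(s[-1] != s[-length(s)])
  n <- n1 + n2
  mu <- 2 * n1 * n2 / n + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  if (v <= 0) return(1)
  2 * stats::pnorm(-abs((runs - mu) / sqrt(v)))
}

#' Forward stepwise covariate selection by cross-validated AUC
#'
#' Procedure: (1) score every candidate alone by cross-validated AUC;
#' (2) order candidates by descending mean AUC; (3) add them in order, keeping
#' a candidate only when it improves the mean CV AUC by at least
#' `tie_epsilon`; (4) when the top two single-covariate AUCs differ by less
#' than `tie_epsilon`, rerun the procedure once per starting covariate and
#' keep the higher-scoring final model; (5) when both members of
#' `tensor_pair` were retained, try replacing their marginal smooths with a
#' tensor-product smooth and keep it if the CV AUC improves; (6) raise a kept
#' term's knots (3 to at most `knots_max`) while a deviance-residual runs test
#' against that covariate fails at `alpha`. The final model is refit on all
#' rows for prediction; reported CV metrics come from the selection-time
#' folds.
#'
#' @param table Standardized case-control data.frame (needs the
#'   `standardization` attribute from [standardize_covariates()]).
#' @param candidates Candidate covariate names (should have passed
#'   [vif_screen()]).
#' @param folds A [fold_scheme()].
#' @param tie_epsilon Minimum AUC improvement / tie width (default 0.01).
#' @param max_terms Maximum number of covariates retained (default 7).
#' @param knots_max Maximum basis dimension when raising knots (default 5).
#' @param alpha Runs-test significance level for the poor-fit check.
#' @param tensor_pair Length-2 covariates eligible for the tensor trial
#'   (default distance and bathymetry), or `NULL` to skip.
#' @inheritParams fit_binomial_gam
#' @return Object of class `habitat_model`: `terms` (ordered, with final
#'   knots), `fit` (`cpf_gam` on all rows), `cv` metrics, `single_aucs`,
#'   `P_a`, `P_u`, `standardization`, `tensor`, `selection` bookkeeping.
#' @export
forward_stepwise <- function(table, candidates, folds, tie_epsilon = 0.01,
                             max_terms = 7L, knots_max = 5L, alpha = 0.05,
                             tensor_pair = c("distance", "bathymetry"),
                             engine = c("auto", "gam", "bam")) {
  engine <- match.arg(engine)
  stopifnot(length(candidates) >= 1)
  single <- vapply(candidates, function(v) {
    cv_evaluate(table, v, folds, engine = engine)$auc[["mean"]]
  }, numeric(1))
  ordered <- names(sort(single, decreasing = TRUE))

  greedy <- function(order_vec) {
    kept <- character(0); best_auc <- 0.5; best_cv <- NULL
    for (v in order_vec) {
      if (length(kept) >= max_terms) break
      cv <- cv_evaluate(table, c(kept, v), folds, engine = engine)
      if (cv$auc[["mean"]] >= best_auc + tie_epsilon) {
        kept <- c(kept, v); best_auc <- cv$auc[["mean"]]; best_cv <- cv
      }
    }
    list(kept = kept, auc = best_auc, cv = best_cv)
  }

  runs <- list(greedy(ordered))
  tie_used <- FALSE
  if (length(ordered) >= 2 &&
      single[ordered[1]] - single[ordered[2]] < tie_epsilon) {
    tie_used <- TRUE
    alt_order <- c(ordered[2], setdiff(ordered, ordered[2]))
    runs[[2]] <- greedy(alt_order)
  }
  best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "auc"))]]
  kept <- best$kept; cv_final <- best$cv; auc_final <- best$auc
  if (length(kept) == 0) {
    warning("no candidate improved on the intercept-only AUC; returning intercept-only model")
  }

  tensor <- NULL
  if (!is.null(tensor_pair) && all(tensor_pair %in% kept)) {
    cv_te <- cv_evaluate(table, kept, folds, tensor = tensor_pair, engine = engine)
    if (cv_te$auc[["mean"]] > auc_final) {
      tensor <- tensor_pair; cv_final <- cv_te; auc_final <- cv_te$auc[["mean"]]
    }
  }

  # knot raising on poor marginal fit (runs test of deviance residuals)
  knots <- stats::setNames(rep(3L, length(kept)), kept)
  if (length(kept)) {
    repeat {
      fit_all <- fit_binomial_gam(table, kept, knots = knots, tensor = tensor,
                                  engine = engine)
      res <- stats::residuals(fit_all$fit, type = "deviance")
      raised <- FALSE
      for (v in setdiff(kept, tensor)) {
        if (knots[v] >= knots_max) next
        if (runs_test_p(res, table[[paste0(v, "_std")]]) < alpha) {
          knots[v] <- knots[v] + 1L; raised <- TRUE
        }
      }
      if (!raised) break
    }
  } else {
    fit_all <- fit_binomial_gam(table, character(0), engine = engine)
  }

  structure(list(
    terms = kept, knots = knots, tensor = tensor, fit = fit_all,
    cv = cv_final, single_aucs = single,
    P_a = mean(table$label == 0), P_u = mean(table$label == 1),
    standardization = attr(table, "standardization"),
    selection = list(order = ordered, tie_used = tie_used,
                     tie_epsilon = tie_epsilon)
  ), class = "habitat_model")
}

#' @export
print.habitat_model <- function(x, ...) {
  cat("<habitat_model>\n terms:",
      if (length(x$terms)) paste(sprintf("%s (k=%d)", x$terms, x$knots[x$terms]),
                                 collapse = " + ") else "(intercept only)", "\n")
  if (!is.null(x$tensor)) cat(" tensor:", paste(x$tensor, collapse = " x "), "\n")
  if (!is.null(x$cv)) {
    cat(sprintf(" CV AUC %.3f +/- %.3f, sens %.3f, spec %.3f (%d folds)\n",
                x$cv$auc[["mean"]], x$cv$auc[["sd"]],
                x$cv$sensitivity[["mean"]], x$cv$specificity[["mean"]],
                x$cv$n_folds_used))
  }
  cat(sprintf(" P_a = %.3f, P_u = %.3f\n", x$P_a, x$P_u))
  invisible(x)
}

#' Serialize / restore a habitat model description
#'
#' Writes the model's term set, knots, coefficients, case-control proportions,
#' standardization parameters and CV metrics as JSON. The JSON documents the
#' model; re-fitting from the table reproduces it exactly given the same
#' seeds.
#'
#' @param model A `habitat_model`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_model_json <- function(model, path) {
  obj <- list(
    terms = model$terms,
    knots = as.list(model$knots),
    tensor = model$tensor,
    coefficients = as.list(stats::coef(model$fit$fit)),
    edf = as.list(model$fit$edf),
    P_a = model$P_a, P_u = model$P_u,
    standardization = model$standardization,
    cv = if (!is.null(model$cv)) list(
      auc = as.list(model$cv$auc), sensitivity = as.list(model$cv$sensitivity),
      specificity = as.list(model$cv$specificity),
      per_fold = model$cv$per_fold) else NULL,
    selection = model$selection,
    engine = model$fit$engine
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
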