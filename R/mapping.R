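# Statistical mapping of the dCH4 climatology: ensembles of single-hidden-layer
# neural networks (20 sigmoid units, L2-regularized) and regression forests
# (bagged CART trees, max 100 splits each), trained on the IHS-transformed
# climatology against gridded environmental predictors with a 70/30 random
# train/validation split per member.

#' Inverse hyperbolic sine transform and its inverse
#'
#' \code{ihs(x) = log(x + sqrt(x^2 + 1))}; a log-like transform that is
#' defined (and odd) for negative disequilibrium, used to keep a handful of
#' very high coastal dCH4 values from dominating training.
#'
#' @param x Value in nM (any real).
#' @return Transformed value; \code{ihs_inverse} is \code{sinh}.
#' @export
ihs <- function(x) asinh(x)

#' @rdname ihs
#' @param y Transformed value.
#' @export
ihs_inverse <- function(y) sinh(y)

mapping_predictors <- c("depth", "sst", "sss", "npp", "poc", "po4", "o2",
                        "hydrate")

# Assemble the predictor columns for a set of cell-months.
predictor_frame <- function(cells, months, depth, predictors,
                            log_depth = TRUE, month_encoding = TRUE) {
  pick <- function(f) {
    if (is.matrix(f)) f[cbind(cells, months)] else f[cells]
  }
  x <- data.frame(
    depth = if (log_depth) log10(depth[cells]) else depth[cells],
    sst = pick(predictors$sst), sss = pick(predictors$sss),
    npp = pick(predictors$npp), poc = pick(predictors$poc),
    po4 = pick(predictors$po4), o2 = pick(predictors$o2),
    hydrate = pick(predictors$hydrate)
  )
  if (month_encoding) {
    x$month_sin <- sin(2 * pi * months / 12)
    x$month_cos <- cos(2 * pi * months / 12)
  }
  x
}

#' Build the training table from a climatology and predictor fields
#'
#' One row per cell-month with data: the IHS-transformed mean dCH4 as target,
#' joined to the predictor climatologies (seafloor depth log10-transformed by
#' default; month entering through a cyclic sin/cos encoding). Rows with any
#' missing predictor are dropped and counted.
#'
#' @param clim An \code{och4_clim}.
#' @param depth Seafloor depth per cell, m.
#' @param predictors Named list of predictor fields (vectors or n_cell x 12
#'   matrices), as from \code{\link{make_predictors}}.
#' @param log_depth,month_encoding Configuration switches.
#' @return Data frame with columns \code{cell}, \code{month}, \code{target}
#'   (IHS nM) and the predictors; attribute \code{dropped} gives the number of
#'   rows lost to missing predictors.
#' @export
build_training_table <- function(clim, depth, predictors, log_depth = TRUE,
                                 month_encoding = TRUE) {
  has <- which(clim$count > 0)
  cells <- ((has - 1L) %% clim$grid$n_cell) + 1L
  months <- ((has - 1L) %/% clim$grid$n_cell) + 1L
  x <- predictor_frame(cells, months, depth, predictors, log_depth,
                       month_encoding)
  tab <- cbind(data.frame(cell = cells, month = months,
                          target = ihs(clim$dch4[has])), x)
  ok <- stats::complete.cases(tab)
  out <- tab[ok, , drop = FALSE]
  if (nrow(out) == 0) stop("build_training_table: no usable rows")
  attr(out, "dropped") <- sum(!ok)
  out
}

#' Predictor table for every ocean cell and month
#'
#' Companion to \code{\link{build_training_table}} covering the full grid, for
#' generating mapped climatologies from trained members.
#'
#' @inheritParams build_training_table
#' @param grid An \code{och4_grid}.
#' @return Data frame with \code{cell}, \code{month} and predictor columns.
#' @export
build_grid_table <- function(grid, depth, predictors, log_depth = TRUE,
                             month_encoding = TRUE) {
  cells <- rep(seq_len(grid$n_cell), times = 12)
  months <- rep(1:12, each = grid$n_cell)
  cbind(data.frame(cell = cells, month = months),
        predictor_frame(cells, months, depth, predictors, log_depth,
                        month_encoding))
}

feature_cols <- function(table) {
  setdiff(names(table), c("cell", "month", "target"))
}

#' Taylor-diagram skill statistics
#'
#' Correlation, centered root-mean-squared difference, and the standard
#' deviation of the predictions normalized by that of the observations. These
#' satisfy the Taylor identity
#' \eqn{cRMSD^2 = s_p^2 + s_o^2 - 2 s_p s_o R}.
#'
#' @param predicted,observed Numeric vectors of equal length.
#' @return Named vector \code{R}, \code{crmsd}, \code{nsd}; \code{R} is
#'   \code{NA} (with a warning) for zero-variance input.
#' @export
taylor_stats <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed))
  # population moments throughout, so the Taylor identity holds exactly
  s_p <- sqrt(mean((predicted - mean(predicted))^2))
  s_o <- sqrt(mean((observed - mean(observed))^2))
  crmsd <- sqrt(mean(((predicted - mean(predicted)) -
                        (observed - mean(observed)))^2))
  if (s_p == 0 || s_o == 0) {
    warning("taylor_stats: zero-variance input; correlation undefined")
    return(c(R = NA_real_, crmsd = crmsd,
             nsd = if (s_o > 0) s_p / s_o else NA_real_))
  }
  c(R = stats::cor(predicted, observed), crmsd = crmsd, nsd = s_p / s_o)
}

#' Train one mapping ensemble member
#'
#' Draws a member-specific random 70/30 train/validation split, fits either a
#' single-hidden-layer neural network (default 20 sigmoid units, linear
#' output, L2 weight decay standing in for Bayesian regularization) or a
#' regression forest (bagged CART trees, each grown on an independent 70% row
#' subsample with at most \code{max_splits} splits), and evaluates held-out
#' skill in IHS space.
#'
#' @param table Training table from \code{\link{build_training_table}} (>= the
#'   configured minimum rows).
#' @param family \code{"ann"} or \code{"rrf"}.
#' @param seed Member seed (controls the split and the fit).
#' @param hidden_units ANN hidden layer size.
#' @param decay ANN L2 penalty weight.
#' @param n_trees,max_splits RRF forest size and per-tree split budget.
#' @param train_frac Training fraction of the row-wise random split.
#' @param min_rows Minimum acceptable number of rows.
#' @param maxit ANN optimizer iteration cap.
#' @return Object of class \code{och4_member} with the fitted model, scaling,
#'   split indices and validation \code{skill} (Taylor statistics).
#' @export
train_member <- function(table, family = c("ann", "rrf"), seed = 1L,
                         hidden_units = 20, decay = 1e-2, n_trees = 50,
                         max_splits = 100, train_frac = 0.7, min_rows = 50,
                         maxit = 200) {
  family <- match.arg(family)
  if (nrow(table) < min_rows)
    stop(sprintf("train_member: %d rows < floor of %d", nrow(table), min_rows))
  feats <- feature_cols(table)
  X <- as.matrix(table[, feats, drop = FALSE])
  y <- table$target

  member <- with_seed(stage_seed(seed, paste0("member_", family)), {
    n <- nrow(table)
    itrain <- sort(sample.int(n, floor(train_frac * n)))
    ival <- setdiff(seq_len(n), itrain)
    if (stats::sd(y[itrain]) == 0) {
      warning("train_member: constant training target; returning constant model")
      fit <- list(constant = mean(y[itrain]))
      list(fit = fit, itrain = itrain, ival = ival, center = NULL, scale = NULL,
           constant = TRUE)
    } else if (family == "ann") {
      ctr <- colMeans(X[itrain, , drop = FALSE])
      scl <- apply(X[itrain, , drop = FALSE], 2, stats::sd)
      scl[scl == 0] <- 1
      Xs <- scale(X, center = ctr, scale = scl)
      fit <- nnet::nnet(Xs[itrain, , drop = FALSE], y[itrain],
                        size = hidden_units, decay = decay, linout = TRUE,
                        maxit = maxit, trace = FALSE, MaxNWts = 20000)
      list(fit = fit, itrain = itrain, ival = ival, center = ctr, scale = scl,
           constant = FALSE)
    } else {
      fit <- randomForest::randomForest(
        X[itrain, , drop = FALSE], y[itrain], ntree = n_trees,
        mtry = ncol(X), replace = FALSE,
        sampsize = max(2L, floor(train_frac * length(itrain))),
        maxnodes = max_splits + 1)  # binary tree: splits = leaves - 1
      list(fit = fit, itrain = itrain, ival = ival, center = NULL,
           scale = NULL, constant = FALSE)
    }
  })
  member$family <- family
  member$seed <- seed
  member$features <- feats
  member$hyper <- list(hidden_units = hidden_units, decay = decay,
                       n_trees = n_trees, max_splits = max_splits)
  class(member) <- "och4_member"
  pv <- predict(member, table[member$ival, , drop = FALSE])
  member$skill <- taylor_stats(pv, y[member$ival])
  member$skill_train <- taylor_stats(
    predict(member, table[member$itrain, , drop = FALSE]), y[member$itrain])
  member
}

#' @export
predict.och4_member <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  if (isTRUE(object$constant))
    return(rep(object$fit$constant, nrow(X)))
  if (object$family == "ann") {
    Xs <- scale(X, center = object$center, scale = object$scale)
    as.numeric(predict(object$fit, Xs))
  } else {
    as.numeric(predict(object$fit, X))
  }
}

#' @export
print.och4_member <- function(x, ...) {
  cat(sprintf("och4_member [%s] seed %d: validation R = %.3f, cRMSD = %.3f, nsd = %.3f\n",
              x$family, x$seed, x$skill[["R"]], x$skill[["crmsd"]],
              x$skill[["nsd"]]))
  invisible(x)
}

#' Select the ANN weight-decay penalty by validation grid search
#'
#' Fits one member per candidate penalty and returns the value with the best
#' held-out correlation.
#'
#' @param table Training table.
#' @param decays Candidate penalties.
#' @param seed Seed for the (shared) split.
#' @param ... Passed to \code{\link{train_member}}.
#' @return The selected decay (attribute \code{skill} carries the search table).
#' @export
select_decay <- function(table, decays = 10^seq(-4, -1), seed = 1L, ...) {
  skill <- vapply(decays, function(d)
    train_member(table, "ann", seed = seed, decay = d, ...)$skill[["R"]],
    numeric(1))
  out <- decays[which.max(skill)]
  attr(out, "skill") <- data.frame(decay = decays, R = skill)
  out
}

#' Train a mapping ensemble and generate gridded dCH4 maps
#'
#' Trains \code{n_members} members per family, each with its own random
#' split/seed, maps the full grid monthly with every member, and
#' back-transforms to nM via \code{sinh}. A member whose training fails is
#' skipped with a message, never aborting the ensemble.
#'
#' @param table Training table.
#' @param grid_table Full-grid predictor table from
#'   \code{\link{build_grid_table}}.
#' @param n_cell Number of grid cells (rows of each monthly map).
#' @param n_members Members per family.
#' @param families Model families to include.
#' @param seed Base seed; member i of family f uses a seed derived from both.
#' @param skill_floor Retention bar on held-out correlation: members with
#'   validation R at or below it are discarded (and logged); extra candidates
#'   are trained (up to twice the quota) to fill the ensemble. \code{NULL}
#'   retains everything.
#' @param ... Hyperparameters passed to \code{\link{train_member}}.
#' @return Object of class \code{och4_ensemble}: per-member monthly maps
#'   (n_cell x 12 matrices, nM), skill table, and member metadata (including
#'   the count of discarded members per family in \code{dropped}).
#' @export
generate_ensemble <- function(table, grid_table, n_cell, n_members = 100,
                              families = c("ann", "rrf"), seed = 1L,
                              skill_floor = 0.75, ...) {
  maps <- list(); meta <- list()
  dropped <- stats::setNames(integer(length(families)), families)
  for (fam in families) {
    kept <- 0L; attempt <- 0L
    while (kept < n_members && attempt < 2L * n_members) {
      attempt <- attempt + 1L
      mseed <- stage_seed(seed, sprintf("ens_%s_%03d", fam, attempt))
      mem <- tryCatch(train_member(table, fam, seed = mseed, ...),
                      error = function(e) {
                        message(sprintf("member %s/%d failed: %s", fam,
                                        attempt, conditionMessage(e)))
                        NULL
                      })
      if (is.null(mem)) next
      if (!is.null(skill_floor) &&
          (is.na(mem$skill[["R"]]) || mem$skill[["R"]] <= skill_floor)) {
        dropped[fam] <- dropped[fam] + 1L
        next
      }
      kept <- kept + 1L
      pred <- ihs_inverse(predict(mem, grid_table))
      maps[[length(maps) + 1L]] <- matrix(pred, n_cell, 12)
      meta[[length(meta) + 1L]] <- data.frame(
        family = fam, member = kept, seed = mseed,
        R = mem$skill[["R"]], crmsd = mem$skill[["crmsd"]],
        nsd = mem$skill[["nsd"]])
    }
  }
  if (length(maps) == 0) stop("generate_ensemble: every member failed")
  out <- list(maps = maps, members = do.call(rbind, meta),
              families = families, n_cell = n_cell, dropped = dropped)
  class(out) <- "och4_ensemble"
  out
}

#' @export
print.och4_ensemble <- function(x, ...) {
  cat(sprintf("och4_ensemble: %d members (%s)\n", length(x$maps),
              paste(sprintf("%s: %d", unique(x$members$family),
                            table(x$members$family)[unique(x$members$family)]),
                    collapse = ", ")))
  cat(sprintf("  validation R: %.3f to %.3f (median %.3f)\n",
              min(x$members$R), max(x$members$R), stats::median(x$members$R)))
  invisible(x)
}

#' Ensemble-mean monthly map
#'
#' @param ensemble An \code{och4_ensemble}.
#' @param family Optional family subset.
#' @return n_cell x 12 matrix, the average of the member maps.
#' @export
ensemble_mean <- function(ensemble, family = NULL) {
  idx <- seq_along(ensemble$maps)
  if (!is.null(family)) idx <- idx[ensemble$members$family == family]
  Reduce(`+`, ensemble$maps[idx]) / length(idx)
}

#' Skill of linear and multiple-linear baselines
#'
#' Ordinary least-squares fits under the same 70/30 split protocol and skill
#' metrics as the machine-learning members, for comparison only: one simple
#' regression per predictor and one multiple regression on all predictors.
#' Aliased (perfectly collinear) columns are dropped with a warning.
#'
#' @param table Training table.
#' @param seed Split seed.
#' @return Data frame: model label, validation R^2 and Taylor statistics.
#' @export
baseline_models <- function(table, seed = 1L) {
  feats <- feature_cols(table)
  with_seed(stage_seed(seed, "baselines"), {
    n <- nrow(table)
    itrain <- sort(sample.int(n, floor(0.7 * n)))
    ival <- setdiff(seq_len(n), itrain)
    eval_fit <- function(fml, label) {
      fit <- stats::lm(fml, data = table[itrain, , drop = FALSE])
      if (anyNA(stats::coef(fit))) {
        bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
        warning(sprintf("baseline_models: dropping collinear terms: %s",
                        paste(bad, collapse = ", ")))
        keep <- setdiff(attr(stats::terms(fit), "term.labels"), bad)
        fit <- stats::lm(stats::reformulate(keep, "target"),
                         data = table[itrain, , drop = FALSE])
      }
      pv <- predict(fit, table[ival, , drop = FALSE])
      st <- taylor_stats(pv, table$target[ival])
      data.frame(model = label, R2 = st[["R"]]^2, R = st[["R"]],
                 crmsd = st[["crmsd"]], nsd = st[["nsd"]])
    }
    single <- do.call(rbind, lapply(feats, function(f)
      eval_fit(stats::reformulate(f, "target"), paste0("lr_", f))))
    mlr <- eval_fit(stats::reformulate(feats, "target"), "mlr")
    rbind(single, mlr)
  })
}
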