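test_that("IHS transform is odd, zero-fixed and exactly invertible", {
  expect_equal(ihs(0), 0)
  x <- c(-100, -1, 0.05, 3, 1500)
  expect_equal(ihs(-x), -ihs(x))
  expect_equal(ihs_inverse(ihs(x)), x, tolerance = 1e-12)
  # log-like behaviour at large argument: ihs(x) ~ ln(2x)
  expect_equal(ihs(1e4), log(2e4), tolerance = 1e-8)
})

test_that("Taylor statistics satisfy their algebraic identities", {
  expect_equal(unname(taylor_stats(1:10, 1:10)), c(1, 0, 1))
  x <- rnorm(50)
  expect_equal(taylor_stats(-x, x)[["R"]], -1)
  set.seed(4)
  for (i in 1:5) {
    p <- rnorm(100); o <- rnorm(100)
    st <- taylor_stats(p, o)
    s_p <- sqrt(mean((p - mean(p))^2)); s_o <- sqrt(mean((o - mean(o))^2))
    expect_equal(st[["crmsd"]]^2,
                 s_p^2 + s_o^2 - 2 * s_p * s_o * st[["R"]], tolerance = 1e-10)
  }
  expect_warning(st0 <- taylor_stats(rep(1, 10), rnorm(10)), "zero-variance")
  expect_true(is.na(st0[["R"]]))
})

test_that("training table join counts rows and drops missing predictors", {
  ch <- chain_small()
  expect_equal(nrow(ch$tab) + attr(ch$tab, "dropped"),
               sum(ch$clim$count > 0))
  expect_false(anyNA(ch$tab))
  # poison one predictor cell and watch the row drop
  w <- ch$world
  preds <- w$predictors
  cell_bad <- ch$tab$cell[1]
  preds$npp[cell_bad, ] <- NA
  tab2 <- build_training_table(ch$clim, w$depth, preds)
  expect_lt(nrow(tab2), nrow(ch$tab))
  expect_equal(nrow(ch$tab) - nrow(tab2), attr(tab2, "dropped"))
})

test_that("member training is deterministic with disjoint splits", {
  ch <- chain_small()
  m1 <- train_member(ch$tab, "ann", seed = 11, maxit = 60)
  m2 <- train_member(ch$tab, "ann", seed = 11, maxit = 60)
  expect_equal(m1$skill, m2$skill)
  expect_identical(m1$itrain, m2$itrain)
  expect_length(intersect(m1$itrain, m1$ival), 0)
  expect_equal(sort(c(m1$itrain, m1$ival)), seq_len(nrow(ch$tab)))
  expect_equal(length(m1$itrain), floor(0.7 * nrow(ch$tab)))
  # held-out predictions match a fresh evaluation (skill computed off-split)
  pv <- predict(m1, ch$tab[m1$ival, ])
  expect_equal(unname(taylor_stats(pv, ch$tab$target[m1$ival])["R"]),
               unname(m1$skill["R"]))
  # rrf path trains and carries the split contract too
  r1 <- train_member(ch$tab, "rrf", seed = 12)
  expect_length(intersect(r1$itrain, r1$ival), 0)
  expect_gt(r1$skill[["R"]], 0.5)
})

test_that("degenerate and undersized training tables are handled", {
  ch <- chain_small()
  tab <- ch$tab[1:100, ]
  tab$target <- 1.5
  # constant target warns once at fit and again in the zero-variance skill
  suppressWarnings(expect_warning(m <- train_member(tab, "ann", seed = 1),
                                  "constant"))
  expect_equal(predict(m, tab[1:5, ]), rep(1.5, 5))
  expect_error(train_member(ch$tab[1:10, ], "ann"), "floor")
})

test_that("ensembles are deterministic, averaged correctly, and logged", {
  ch <- chain_small()
  e1 <- generate_ensemble(ch$tab, ch$gtab, ch$world$grid$n_cell,
                          n_members = 1, families = "rrf", seed = 3,
                          skill_floor = NULL)
  # n = 1: ensemble mean equals the single member's map
  expect_equal(ensemble_mean(e1), e1$maps[[1]])
  e2 <- generate_ensemble(ch$tab, ch$gtab, ch$world$grid$n_cell,
                          n_members = 1, families = "rrf", seed = 3,
                          skill_floor = NULL)
  expect_identical(e1$maps, e2$maps)
  # maps are finite after back-transform
  expect_true(all(is.finite(e1$maps[[1]])))
  # averaging reduces variance
  e4 <- generate_ensemble(ch$tab, ch$gtab, ch$world$grid$n_cell,
                          n_members = 3, families = c("ann", "rrf"), seed = 3,
                          skill_floor = NULL, maxit = 60)
  expect_lte(var(as.numeric(ensemble_mean(e4))),
             max(sapply(e4$maps, function(m) var(as.numeric(m)))))
  # an impossible retention bar empties the ensemble
  expect_error(
    suppressMessages(generate_ensemble(ch$tab, ch$gtab, ch$world$grid$n_cell,
                                       n_members = 2, families = "rrf",
                                       seed = 3, skill_floor = 0.9999)),
    "every member failed")
})

test_that("baseline regressions behave as linear references", {
  # a perfectly linear target is recovered with R^2 = 1 by the MLR
  set.seed(9)
  n <- 300
  tab <- data.frame(cell = 1:n, month = 1L, depth = runif(n, 1, 3),
                    sst = runif(n, 0, 30), npp = runif(n, 100, 900))
  tab$target <- 2 * tab$depth - 0.01 * tab$npp + 1
  bl <- baseline_models(tab, seed = 2)
  expect_equal(bl$R2[bl$model == "mlr"], 1, tolerance = 1e-9)
  # shuffled target carries no skill
  tab$target <- sample(tab$target)
  bl0 <- baseline_models(tab, seed = 2)
  expect_lt(bl0$R2[bl0$model == "mlr"], 0.08)
  # nonlinear truth: machine-learning families beat the MLR on the same
  # table (single members fluctuate, so compare the median of three)
  ch <- chain_small()
  blw <- baseline_models(ch$tab, seed = 2)
  ann_r2 <- sapply(c(2, 5, 9), function(s)
    train_member(ch$tab, "ann", seed = s, maxit = 120)$skill[["R"]]^2)
  expect_gt(median(ann_r2), blw$R2[blw$model == "mlr"])
  rrf <- train_member(ch$tab, "rrf", seed = 2)
  expect_gt(rrf$skill[["R"]]^2, blw$R2[blw$model == "mlr"])
})

test_that("growing the hidden layer overfits training before validation", {
  ch <- chain_small()
  fit <- lapply(c(5, 20, 80), function(h)
    train_member(ch$tab, "ann", seed = 21, hidden_units = h, maxit = 120))
  r_train <- sapply(fit, function(m) m$skill_train[["R"]])
  r_val <- sapply(fit, function(m) m$skill[["R"]])
  # training fit improves with complexity
  expect_gt(r_train[3], r_train[1])
  # validation skill plateaus: the 80-unit gain over 20 units is marginal
  expect_lt(r_val[3] - r_val[2], 0.05)
})

test_that("decay selection searches the validation split", {
  ch <- chain_small()
  d <- select_decay(ch$tab[1:400, ], decays = c(1e-3, 1e-1), seed = 4,
                    maxit = 50)
  expect_true(d %in% c(1e-3, 1e-1))
  expect_equal(nrow(attr(d, "skill")), 2L)
})
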