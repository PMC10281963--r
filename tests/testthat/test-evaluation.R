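test_that("Fnat is the recovered fraction of native contacts", {
  b <- tiny_bundle()
  native <- b[[1]]$native
  expect_equal(compute_fnat(native, native), 1.0)
  far <- native
  far$chains[[2]] <- transform_chain(native$chains[[2]], diag(3),
                                     c(50, 0, 0))
  expect_equal(compute_fnat(far, native), 0.0)
  expect_error(compute_fnat(native, far), "no inter-chain contacts")
})

test_that("Fnat counts planted contacts against a brute-force enumeration", {
  b <- tiny_bundle()
  native <- b[[1]]$native
  dec <- b[[1]]$decoy_set$decoys[[8]]
  got <- compute_fnat(dec, native)
  # brute force over residue pairs and atoms
  atoms <- function(cplx, ch)
    ifaceqe:::chain_atoms(cplx$chains[[ch]])
  contacts <- function(cplx) {
    a1 <- atoms(cplx, 1); a2 <- atoms(cplx, 2)
    out <- matrix(FALSE, cplx$L1, cplx$L2)
    for (p in seq_along(a1$res))
      for (q in seq_along(a2$res))
        if (sum((a1$xyz[p, ] - a2$xyz[q, ])^2) < 25)
          out[a1$res[p], a2$res[q]] <- TRUE
    out
  }
  nat <- contacts(native); mod <- contacts(dec)
  expect_equal(got, sum(nat & mod) / sum(nat), tolerance = 1e-12)
})

test_that("ligand RMSD reports pure translations exactly", {
  b <- tiny_bundle()
  native <- b[[1]]$native
  expect_equal(compute_lrms(native, native), 0, tolerance = 1e-9)
  shifted <- native
  shifted$chains[[2]] <- transform_chain(native$chains[[2]], diag(3),
                                         8.5 * c(1, 0, 0) / 1)
  expect_equal(compute_lrms(shifted, native), 8.5, tolerance = 1e-9)
})

test_that("ligand RMSD with a perturbed receptor matches a two-step oracle", {
  set.seed(81)
  b <- tiny_bundle()
  native <- b[[1]]$native
  model <- native
  model$chains[[1]] <- jitter <- ifaceqe:::jitter_chain(native$chains[[1]], 0.3)
  model$chains[[2]] <- transform_chain(native$chains[[2]],
                                       rotation_matrix(c(1, 1, 0), 0.2),
                                       c(2, -1, 0.5))
  got <- compute_lrms(model, native)
  # independent two-step computation using bio3d superposition
  stack_bb <- function(chain) {
    m <- do.call(rbind, lapply(c("N", "CA", "C", "O"), function(el)
      chain[[el]]))
    m[is.finite(m[, 1]), , drop = FALSE]
  }
  recm <- stack_bb(model$chains[[1]]); recn <- stack_bb(native$chains[[1]])
  lig_m <- stack_bb(model$chains[[2]]); lig_n <- stack_bb(native$chains[[2]])
  # bio3d fits on the receptor subset and transforms everything
  allm <- rbind(recm, lig_m)
  alln <- rbind(recn, matrix(0, nrow(lig_m), 3))  # ligand part unused in fit
  fit_mask <- rep(c(TRUE, FALSE), c(nrow(recm), nrow(lig_m)))
  moved <- matrix(bio3d::rot.lsq(xx = as.numeric(t(allm)),
                                 yy = as.numeric(t(alln)),
                                 xfit = rep(fit_mask, each = 3)),
                  ncol = 3, byrow = TRUE)
  ref <- sqrt(mean(rowSums((moved[!fit_mask, , drop = FALSE] - lig_n)^2)))
  expect_equal(got, ref, tolerance = 1e-6)
})

test_that("interface RMSD matches an independent reimplementation", {
  set.seed(82)
  b <- tiny_bundle()
  native <- b[[1]]$native
  expect_equal(compute_irms(native, native), 0, tolerance = 1e-9)
  dec <- b[[1]]$decoy_set$decoys[[4]]
  got <- compute_irms(dec, native)
  # oracle: recompute from definitions with separate code
  x1 <- interaction_coordinate(native$chains[[1]])
  x2 <- interaction_coordinate(native$chains[[2]])
  close1 <- c(); close2 <- c()
  for (i in seq_len(nrow(x1)))
    for (j in seq_len(nrow(x2)))
      if (sqrt(sum((x1[i, ] - x2[j, ])^2)) < 10) {
        close1 <- union(close1, i); close2 <- union(close2, j)
      }
  stack_iface <- function(cplx) {
    rows <- NULL
    for (ch in 1:2) {
      res <- if (ch == 1) sort(close1) else sort(close2)
      for (el in c("N", "CA", "C", "O"))
        rows <- rbind(rows, cplx$chains[[ch]][[el]][res, , drop = FALSE])
    }
    rows[is.finite(rows[, 1]), , drop = FALSE]
  }
  A <- stack_iface(dec); B <- stack_iface(native)
  expect_equal(got, superpose_kabsch(A, B)$rmsd, tolerance = 1e-6)
})

test_that("DockQ combines its terms with the standard constants and classes", {
  expect_equal(compute_dockq(1, 0, 0)$dockq, 1.0)
  expect_equal(compute_dockq(0.5, 8.5, 1.5)$dockq, 0.5)
  expect_lt(compute_dockq(0, 1e9, 1e9)$dockq, 1e-6)
  expect_equal(compute_dockq(0.1, 30, 10)$capri_class, "incorrect")
  expect_equal(compute_dockq(0.5, 8.5, 1.5)$capri_class, "medium")
  expect_equal(compute_dockq(1, 0, 0)$capri_class, "high")
  # class boundaries, built from exact term combinations
  expect_equal(compute_dockq(0.6897, 1e9, 1e9)$capri_class, "incorrect")
  expect_equal(compute_dockq(0.69, 1e9, 1e9)$capri_class, "acceptable")
  expect_equal(compute_dockq(0.47, 0, 1e9)$capri_class, "medium")  # 0.49
  expect_equal(compute_dockq(0.43, 0, 0)$capri_class, "high")      # 0.81
})

test_that("a native scored against itself is high quality", {
  b <- tiny_bundle()
  for (tg in b) {
    dq <- dockq_score(tg$native, tg$native)
    expect_equal(dq$dockq, 1.0, tolerance = 1e-9)
    expect_equal(dq$capri_class, "high")
  }
})

test_that("success and hit rates reproduce constructed tables", {
  # 4 targets, 5 decoys each; exactly 3 targets have an acceptable decoy
  # somewhere in their top-5
  tab <- ranking_table(
    target = rep(c("t1", "t2", "t3", "t4"), each = 5),
    decoy = paste0("d", 1:20),
    score = c(5:1, 5:1, 5:1, 5:1),
    dockq = c(0.5, 0, 0, 0, 0,      # t1: top-1 acceptable
              0, 0, 0, 0, 0.4,      # t2: acceptable at rank 5
              0, 0.3, 0, 0, 0,      # t3: acceptable at rank 2
              0, 0, 0, 0, 0))       # t4: none
  expect_equal(success_rate(tab, 5), 75)
  expect_equal(success_rate(tab, 1), 25)
  expect_equal(hit_rate(tab, 1), 100 / 3, tolerance = 1e-9)
  # M = 8 with exactly 3 captured in the top-2
  tab2 <- ranking_table(
    target = rep(c("a", "b"), each = 6),
    decoy = paste0("d", 1:12),
    score = c(6:1, 6:1),
    dockq = c(0.9, 0.8, 0, 0.5, 0.6, 0,
              0.7, 0, 0, 0.3, 0.4, 0.25))
  expect_equal(sum(tab2$dockq >= 0.23), 8)
  expect_equal(hit_rate(tab2, 2), 100 * 3 / 8)
})

test_that("rates match the brute-force oracle and are monotone in N", {
  set.seed(83)
  for (k in 1:60) {
    K <- sample(2:5, 1)
    tab <- ranking_table(
      target = rep(paste0("t", 1:K), each = 6),
      decoy = paste0("d", 1:(6 * K)),
      score = round(runif(6 * K), 2),     # rounded scores force ties
      dockq = sample(c(0, 0.1, 0.23, 0.5, 0.9), 6 * K, replace = TRUE))
    if (sum(tab$dockq >= 0.23) == 0) next
    prev_sr <- 0; prev_hr <- 0
    for (N in c(1, 2, 4, 6)) {
      ref <- oracle_sr_hr(tab, N)
      expect_equal(success_rate(tab, N), ref$sr, tolerance = 1e-12)
      expect_equal(hit_rate(tab, N), ref$hr, tolerance = 1e-12)
      expect_gte(ref$sr, prev_sr); expect_gte(ref$hr, prev_hr)
      prev_sr <- ref$sr; prev_hr <- ref$hr
    }
  }
})

test_that("ranking ties break stably by input order", {
  tab <- ranking_table(target = rep("t", 3), decoy = c("a", "b", "c"),
                       score = c(1, 1, 1), dockq = c(0, 0.5, 0.5))
  # top-1 must be decoy 'a' (input order on tied scores): not acceptable
  expect_equal(success_rate(tab, 1), 0)
  expect_equal(success_rate(tab, 2), 100)
})

test_that("Spearman correlation uses average ranks on ties", {
  expect_equal(score_correlation(1:5, 1:5), 1)
  expect_equal(score_correlation(1:5, -(1:5)), -1)
  pred <- c(0.1, 0.4, 0.4, 0.7, 0.9)
  truth <- c(0.0, 0.2, 0.5, 0.6, 1.0)
  expect_equal(score_correlation(pred, truth),
               oracle_spearman(pred, truth), tolerance = 1e-12)
  expect_warning(v <- score_correlation(rep(1, 5), 1:5), "zero variance")
  expect_true(is.na(v))
})

test_that("ROC-AUC equals exhaustive pair counting with half ties", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(F, F, F, T, T)), 1)
  set.seed(84)
  for (k in 1:40) {
    n <- sample(6:14, 1)
    score <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # ties likely
    lab <- runif(n) < 0.5
    if (!any(lab) || all(lab)) next
    expect_equal(roc_auc(score, lab), oracle_auc(score, lab),
                 tolerance = 1e-12)
  }
  # large-sample null is near one half
  set.seed(85)
  expect_lt(abs(roc_auc(runif(4000), runif(4000) < 0.5) - 0.5), 0.05)
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("ROC-AUC agrees with pROC", {
  set.seed(86)
  score <- rnorm(60)
  lab <- (score + rnorm(60)) > 0
  ref <- as.numeric(suppressMessages(pROC::auc(pROC::roc(lab, score,
                                                         quiet = TRUE))))
  expect_equal(roc_auc(score, lab), ref, tolerance = 1e-9)
})

test_that("min-max normalization maps best energy to one", {
  expect_equal(minmax_normalize(c(-10, 0, 10)), c(1, 0.5, 0))
  raw <- c(3, -7, 2, 0)
  norm <- minmax_normalize(raw)
  expect_equal(norm[which.min(raw)], 1)
  expect_equal(norm[which.max(raw)], 0)
  expect_equal(order(norm), rev(order(raw)))  # order reversed
  expect_error(minmax_normalize(c(2, 2, 2)), "all values equal")
})

test_that("ranking summaries and TSV outputs are consistent", {
  set.seed(87)
  tab <- ranking_table(target = rep(c("x", "y"), each = 10),
                       decoy = paste0("d", 1:20),
                       score = runif(20),
                       dockq = runif(20))
  ev <- evaluate_ranking(tab, Ns = c(1, 5, 10))
  expect_equal(ev$summary$N, c(1, 5, 10))
  expect_equal(ev$summary$SR[3], 100)  # N covers all decoys
  expect_equal(ev$summary$HR[3], 100)
  expect_equal(ev$spearman, score_correlation(tab$score, tab$dockq))
  dir <- withr::local_tempdir()
  paths <- write_evaluation(tab, dir, Ns = c(1, 5, 10))
  summ <- read.delim(paths$summary)
  expect_equal(summ$SR, ev$summary$SR)
  per <- read.delim(paths$per_decoy)
  expect_equal(nrow(per), 20)
})
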