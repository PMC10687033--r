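test_that("built-in signatures have the published sizes and content", {
  sigs <- builtinSignatures()
  expect_equal(length(sigs$TEMRA), 36)
  expect_equal(length(sigs$MacroCXCL10), 16)
  expect_equal(length(sigs$combined), 52)   # the two lists are disjoint
  expect_length(intersect(signatureGenes(sigs$TEMRA),
                          signatureGenes(sigs$MacroCXCL10)), 0)
  expect_true(all(c("GZMH", "KRLK1") %in% signatureGenes(sigs$TEMRA)))
  expect_true(all(c("CXCL10", "WARS") %in%
                    signatureGenes(sigs$MacroCXCL10)))

  fixed <- builtinSignatures(fix_symbols = TRUE)
  expect_true("KLRK1" %in% signatureGenes(fixed$TEMRA))
  expect_false("KRLK1" %in% signatureGenes(fixed$TEMRA))
  expect_true("WARS1" %in% signatureGenes(fixed$MacroCXCL10))
  expect_equal(length(fixed$combined), 52)
})

test_that("signature files round-trip through the plain-text format", {
  path <- tempfile(fileext = ".txt")
  writeLines(c("# setA", "G1", "G2", "# setB", "G3"), path)
  sigs <- readSignatures(path)
  expect_equal(names(sigs), c("setA", "setB"))
  expect_equal(signatureGenes(sigs$setA), c("G1", "G2"))
  writeLines(c("G1"), path)
  expect_error(readSignatures(path), "header")
})

make_toy_expr <- function(G = 20, n = 4, seed = 61) {
  set.seed(seed)
  m <- matrix(rexp(G * n), G, n,
              dimnames = list(paste0("G", seq_len(G)),
                              paste0("S", seq_len(n))))
  m
}

test_that("ssGSEA running sum matches the literal step-by-step oracle", {
  expr <- make_toy_expr()
  sig <- GeneSignature("toy", paste0("G", 1:5))
  got <- ssgseaScores(expr, sig, normalize = FALSE)
  want <- oracle_ssgsea(expr, rownames(expr) %in% signatureGenes(sig))
  expect_equal(got$score, unname(want), tolerance = 1e-12)

  # normalization divides by the cross-sample range
  norm <- ssgseaScores(expr, sig, normalize = TRUE)
  expect_equal(norm$score, got$score / diff(range(got$score)),
               tolerance = 1e-12)
})

test_that("ssGSEA is rank-based and deterministic", {
  expr <- make_toy_expr(G = 30, n = 3, seed = 62)
  sig <- GeneSignature("toy", paste0("G", c(2, 9, 17)))
  base <- ssgseaScores(expr, sig, normalize = FALSE)
  # strictly monotone per-sample transform leaves scores untouched
  expect_equal(ssgseaScores(exp(expr), sig, normalize = FALSE)$score,
               base$score, tolerance = 1e-12)
  # identical expression vectors give identical scores
  dup <- cbind(expr, `S4` = expr[, 1])
  sc <- ssgseaScores(dup, sig, normalize = FALSE)
  expect_equal(sc$score[4], sc$score[1], tolerance = 1e-12)
})

test_that("samples whose signature genes top the ranking score highest", {
  set.seed(63)
  G <- 40
  expr <- matrix(runif(G * 3, 1, 2), G, 3,
                 dimnames = list(paste0("G", 1:G), paste0("S", 1:3)))
  sig_genes <- paste0("G", 1:6)
  expr[sig_genes, 1] <- 10 + runif(6)      # top ranks in sample 1 only
  sc <- ssgseaScores(expr, GeneSignature("toy", sig_genes),
                     normalize = FALSE)
  expect_gt(sc$score[1], 0)
  expect_equal(which.max(sc$score), 1L)
})

test_that("missing signature genes warn, an empty overlap errors", {
  expr <- make_toy_expr()
  expect_warning(
    sc <- ssgseaScores(expr, GeneSignature("partial",
                                           c("G1", "G2", "NOPE")),
                       normalize = FALSE), "NOPE")
  expect_equal(nrow(sc), 4)
  expect_error(ssgseaScores(expr, GeneSignature("none", c("X1", "X2"))),
               "none")
  # case-insensitive matching after trimming
  sc2 <- ssgseaScores(expr, GeneSignature("case", c(" g1 ", "g2")),
                      normalize = FALSE)
  sc3 <- ssgseaScores(expr, GeneSignature("case", c("G1", "G2")),
                      normalize = FALSE)
  expect_equal(sc2$score, sc3$score)
})

test_that("median split sends median ties to the low group", {
  s <- setNames(c(1, 2, 3, 4), paste0("S", 1:4))
  g <- splitByMedian(s)
  expect_equal(unname(g), c("low", "low", "high", "high"))

  tie <- setNames(c(1, 2, 2, 3), paste0("S", 1:4))
  g2 <- splitByMedian(tie)
  expect_equal(names(g2)[g2 == "high"], "S4")

  expect_error(splitByMedian(setNames(rep(1, 5), paste0("S", 1:5))),
               "identical")

  set.seed(64)
  s <- setNames(rnorm(100), paste0("S", 1:100))
  g3 <- splitByMedian(s)
  # sort-based oracle: high exactly when strictly above the middle value
  med <- mean(sort(s)[50:51])
  expect_equal(unname(g3 == "high"), unname(s > med))
})

test_that("maxstat scan equals an exhaustive survdiff-based scan", {
  set.seed(65)
  for (i in 1:5) {
    n <- 30
    s <- rnorm(n)
    time <- rexp(n, rate = ifelse(s > 0, 1 / 20, 1 / 5))
    event <- rbinom(n, 1, 0.8)
    got <- maxstatCutpoint(setNames(s, paste0("S", 1:n)), time, event)
    want <- oracle_maxstat(s, time, event)
    expect_equal(got$scan$candidate, want$candidate, tolerance = 1e-12)
    expect_equal(got$scan$statistic, want$statistic, tolerance = 1e-8)
    expect_equal(got$cutpoint,
                 want$candidate[which.max(want$statistic)])
    expect_equal(got$statistic, max(want$statistic), tolerance = 1e-8)
  }
})

test_that("maxstat separates well-separated score clusters", {
  set.seed(66)
  n <- 40
  s <- c(rnorm(20, 0, 0.3), rnorm(20, 5, 0.3))
  time <- c(rexp(20, 1 / 3), rexp(20, 1 / 30))
  event <- rep(1, n)
  res <- maxstatCutpoint(setNames(s, paste0("S", 1:n)), time, event)
  expect_gt(res$cutpoint, max(s[1:20]) - 1e-9)
  expect_lt(res$cutpoint, min(s[21:40]))

  # permuting survival against score deflates the chosen statistic
  perm <- maxstatCutpoint(setNames(s, paste0("S", 1:n)),
                          sample(time), sample(event))
  expect_lt(perm$statistic, res$statistic)

  # the selected statistic dominates the median split's statistic
  med_stat <- sqrt(survival::survdiff(
    survival::Surv(time, event) ~ I(s <= stats::median(s)))$chisq)
  expect_gte(res$statistic + 1e-8, med_stat)
})

test_that("maxstat enforces its preconditions", {
  expect_error(maxstatCutpoint(setNames(rnorm(5), paste0("S", 1:5)),
                               rexp(5), rep(1, 5)), "at least 10")
  s <- setNames(rnorm(12), paste0("S", 1:12))
  expect_error(maxstatCutpoint(s, rexp(12), rep(0, 12)), "event")
  expect_error(maxstatCutpoint(s, rexp(12), rep(1, 12),
                               min_prop = 0.6, max_prop = 0.9),
               "admissible")
})

test_that("KM/log-rank matches a hand-computed risk table", {
  # 12-subject worked table, two groups
  time <- c(2, 4, 4, 6, 8, 10, 3, 5, 7, 7, 9, 12)
  event <- c(1, 1, 0, 1, 1, 0, 1, 1, 1, 0, 1, 1)
  group <- rep(c("A", "B"), each = 6)
  res <- kmLogrank(time, event, group)
  want <- oracle_logrank(time, event, group == "A")
  expect_equal(res$logrank_chi2, want$chi2, tolerance = 1e-8)
  expect_equal(res$logrank_p,
               pchisq(want$chi2, 1, lower.tail = FALSE),
               tolerance = 1e-8)
  for (g in c("A", "B")) {
    km <- oracle_km(time[group == g], event[group == g])
    sub <- res$curves[res$curves$group == g, ]
    expect_equal(sub$surv, km$surv[km$time %in% sub$time],
                 tolerance = 1e-12)
    # median: first time the estimate drops to 0.5 or below
    med <- km$time[km$surv <= 0.5][1]
    expect_equal(unname(res$median[g]), med)
  }
})

test_that("KM limits: identical groups, no events, no censoring", {
  time <- c(1, 2, 3, 4)
  event <- c(1, 0, 1, 1)
  res <- kmLogrank(c(time, time), c(event, event),
                   rep(c("A", "B"), each = 4))
  expect_equal(res$logrank_chi2, 0, tolerance = 1e-12)
  expect_equal(res$logrank_p, 1, tolerance = 1e-12)

  none <- kmLogrank(c(1, 2, 3, 4), rep(0, 4), c("A", "A", "B", "B"))
  expect_true(all(none$curves$surv == 1))
  expect_true(all(is.na(none$median)))
  expect_equal(none$logrank_chi2, 0)
  expect_equal(none$logrank_p, 1)

  # uncensored KM equals the empirical survivor function
  set.seed(67)
  t2 <- sort(rexp(30))
  res2 <- kmLogrank(c(t2, t2 + 100), rep(1, 60),
                    rep(c("A", "B"), each = 30))
  a <- res2$curves[res2$curves$group == "A", ]
  expect_equal(a$surv, 1 - ecdf(t2)(a$time), tolerance = 1e-12)

  expect_error(kmLogrank(c(1, 2), c(1, 1), c("A", "A")), "two groups")
  expect_error(kmLogrank(c(0, 2), c(1, 1), c("A", "B")), "positive")
})

test_that("expression and survival tables round-trip through disk", {
  expr <- make_toy_expr(G = 6, n = 3, seed = 68)
  tsv <- tempfile(fileext = ".tsv")
  write.table(data.frame(gene = rownames(expr), expr,
                         check.names = FALSE),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- readExpressionMatrix(tsv)
  expect_equal(back, expr, tolerance = 1e-12)

  # MatrixMarket triplet + name files
  mtx <- tempfile(fileext = ".mtx")
  Matrix::writeMM(Matrix::Matrix(expr, sparse = TRUE), mtx)
  gf <- tempfile(); sf <- tempfile()
  writeLines(rownames(expr), gf)
  writeLines(colnames(expr), sf)
  back2 <- readExpressionMatrix(mtx, genes = gf, samples = sf)
  expect_equal(back2, expr, tolerance = 1e-12)

  sv <- data.frame(sample_id = c("S1", "S2"), arm = "atezo_bev",
                   os_time = c(3.5, 10), os_event = c(1, 0),
                   pfs_time = c(2, 8), pfs_event = c(1, 1))
  csv <- tempfile(fileext = ".csv")
  write.csv(sv, csv, row.names = FALSE)
  expect_equal(readSurvivalTable(csv), sv)
})
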