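# Small hand-built probability matrix + label fixture used across blocks.
toy_dtnt <- function() {
  cls <- c("A", "B", "C", "N")
  p <- matrix(runif(6 * 4), 6, 4,
              dimnames = list(sprintf("d%d", 1:6), cls))
  labels <- list(d1 = "N", d2 = c("A", "N"), d3 = "B", d4 = "C",
                 d5 = c("B", "C"), d6 = "A")
  build_dtn_t(p, labels)
}

test_that("DTN-T zeroes exactly the known-label cells", {
  cls <- c("A", "B", "C", "N")
  p <- matrix(0.2, 2, 4, dimnames = list(c("d1", "d2"), cls))
  p["d1", "N"] <- 0.9
  dtnt <- build_dtn_t(p, list(d1 = "N", d2 = cls))
  expect_equal(unname(dtnt$p["d1", ]), c(0.2, 0.2, 0.2, 0))
  expect_equal(unname(dtnt$p["d2", ]), rep(0, 4))   # all-label drug: zero row

  set.seed(71)
  dt <- toy_dtnt()
  labels <- dt$labels
  expect_equal(sum(dt$p == 0), sum(lengths(labels)))  # tally oracle
  expect_error(build_dtn_t(dt$p, labels[-1]), "without labels")
})

test_that("pruning is monotone in the threshold", {
  set.seed(72)
  dt <- toy_dtnt()
  e_lo <- prune_dtn(dt, 0.3)
  e_hi <- prune_dtn(dt, 0.7)
  expect_true(all(e_hi <= e_lo))
  expect_equal(prune_dtn(dt, 0), (dt$p >= 0) * 1L)
  p1 <- dt$p; p1["d1", "A"] <- 1
  dt1 <- build_dtn_t(p1, dt$labels)
  e1 <- prune_dtn(dt1, 1)
  expect_equal(sum(e1), 1L)
  expect_equal(e1["d1", "A"], 1L)
})

test_that("enrichment ratios follow the (a/b)/(c/d) contingency definition", {
  r <- list(er = (2 / 4) / (5 / 10))
  expect_equal(r$er, 1)

  # a = 0 forces ER = 0
  cls <- c("A", "B")
  edges <- matrix(c(0, 1, 0, 0), 2, 2, dimnames = list(c("d1", "d2"), cls))
  labels <- list(d1 = "B", d2 = "B")
  expect_equal(enrichment_ratio(edges, labels, "A", "B")$er, 0)

  # 10-drug random edge set: every ordered pair matches the counting oracle
  set.seed(73)
  cls4 <- c("A", "B", "C", "N")
  drugs <- sprintf("d%02d", 1:10)
  labels10 <- lapply(seq_along(drugs), function(i) {
    sample(cls4, sample(1:2, 1))
  })
  names(labels10) <- drugs
  edges10 <- matrix(rbinom(40, 1, 0.35), 10, 4,
                    dimnames = list(drugs, cls4))
  for (d in drugs) edges10[d, labels10[[d]]] <- 0  # known labels carry no edge
  for (x in cls4) {
    for (y in setdiff(cls4, x)) {
      got <- enrichment_ratio(edges10, labels10, x, y)
      expect_equal(got$er, er_oracle(edges10, labels10, x, y))
      expect_true(got$a <= got$b && got$b <= got$d)
      expect_true(got$a <= got$c && got$c <= got$d)
    }
  }
})

test_that("the ER matrix stores counts and a missing diagonal", {
  set.seed(74)
  dt <- toy_dtnt()
  er <- er_matrix(dt, 0.4)
  expect_true(all(is.na(diag(er))))
  expect_true(all(er[row(er) != col(er)] >= 0))
  counts <- attr(er, "counts")
  expect_equal(dim(counts), c(4L, 4L, 4L))
})

test_that("threshold-stability correlations match a direct oracle", {
  set.seed(75)
  cls <- c("A", "B", "C", "N")
  p <- matrix(runif(40 * 4), 40, 4,
              dimnames = list(sprintf("d%02d", 1:40), cls))
  labels <- stats::setNames(as.list(sample(cls, 40, replace = TRUE)),
                            rownames(p))
  dt <- build_dtn_t(p, labels)
  grid <- c(0.2, 0.3, 0.4)
  rho <- er_threshold_stability(dt, grid)
  expect_equal(rho, t(rho), ignore_attr = TRUE)
  expect_equal(unname(diag(rho)), rep(1, 3))
  # direct oracle for one off-diagonal pair
  e1 <- er_matrix(dt, 0.2); e2 <- er_matrix(dt, 0.4)
  v1 <- e1[row(e1) != col(e1)]; v2 <- e2[row(e2) != col(e2)]
  ok <- is.finite(v1) & is.finite(v2)
  expect_equal(rho[1, 3], cor_oracle(v1[ok], v2[ok]))
})

test_that("combining ER matrices averages cellwise", {
  set.seed(76)
  dt <- toy_dtnt()
  # a single repeated threshold: combined equals the per-threshold matrix
  single <- er_matrix(dt, 0.5)
  comb_same <- combined_er(dt, c(0.5, 0.5, 0.5))
  expect_equal(comb_same, single, ignore_attr = TRUE)
  # two-threshold mean
  ea <- er_matrix(dt, 0.3); eb <- er_matrix(dt, 0.6)
  comb <- combined_er(dt, c(0.3, 0.6))
  off <- row(comb) != col(comb)
  expect_equal(comb[off], ((ea + eb) / 2)[off])
})

test_that("top ER pairs sort descending with a lexicographic tie-break", {
  er <- matrix(1, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  diag(er) <- NA
  top1 <- top_er_pairs(er, 1)
  expect_identical(top1$from, "A")
  expect_identical(top1$to, "B")
  expect_equal(nrow(top_er_pairs(er, 100)), 6)

  set.seed(77)
  er2 <- matrix(runif(9), 3, 3, dimnames = dimnames(er))
  diag(er2) <- NA
  got <- top_er_pairs(er2, 3)
  vals <- sort(er2[is.finite(er2)], decreasing = TRUE)[1:3]
  expect_equal(got$er, vals)
})

test_that("a latent class planted into one label community enriches that cell", {
  # latent class N planted only into A-labelled drugs: ER_{A,N} should
  # exceed the median off-diagonal ER
  cls <- c("A", "B", "C", "N")
  drugs <- sprintf("d%02d", 1:40)
  labels <- stats::setNames(as.list(rep(c("A", "B", "C"), length.out = 40)),
                            drugs)
  set.seed(78)
  p <- matrix(runif(160, 0, 0.3), 40, 4, dimnames = list(drugs, cls))
  a_drugs <- drugs[vapply(labels, function(l) "A" %in% l, NA)]
  p[a_drugs, "N"] <- runif(length(a_drugs), 0.7, 1)
  dt <- build_dtn_t(p, labels)
  er <- combined_er(dt, c(0.5, 0.6, 0.7))
  off <- er[row(er) != col(er)]
  expect_gt(er["A", "N"], stats::median(off, na.rm = TRUE))
})
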