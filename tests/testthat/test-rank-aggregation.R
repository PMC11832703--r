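test_that("within-file ranking uses absolute weights with tie-averaging", {
  s <- make_score("P", c("x", "y", "z"), c(-0.9, 0.5, 0.1))
  expect_equal(rank_within_file(s), c(x = 1, y = 2, z = 3))
  s2 <- make_score("P", c("x", "y", "z"), c(0.5, -0.5, 0.1))
  expect_equal(rank_within_file(s2), c(x = 1.5, y = 1.5, z = 3))
  s3 <- make_score("P", "only", 0.42)
  expect_equal(rank_within_file(s3), c(only = 1))
  empty <- score_file("P", data.frame(rsid = character(),
                                      effect_weight = numeric()))
  expect_error(rank_within_file(empty), "empty")
})

test_that("the rank matrix fills missing variants with N exactly", {
  m <- build_rank_matrix(micro_files())
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(m["a", ], c(PGS1 = 2, PGS2 = 3))
  expect_equal(m["b", ], c(PGS1 = 1, PGS2 = 2))
  expect_equal(m["c", ], c(PGS1 = 3, PGS2 = 1))

  # one file: matrix equals the within-file ranking, no N-fill
  one <- build_rank_matrix(micro_files()[1])
  expect_equal(as.numeric(one[c("a", "b"), 1]), c(2, 1))

  # present-variant ranks in each column sum to m(m+1)/2
  set.seed(3)
  files <- lapply(1:4, function(j) {
    k <- sample(3:10, 1)
    make_score(sprintf("P%d", j), sample(paste0("rs", 1:15), k), rnorm(k))
  })
  mm <- build_rank_matrix(files)
  for (j in seq_along(files)) {
    own <- files[[j]]$variants$rsid
    expect_equal(sum(mm[own, j]), length(own) * (length(own) + 1) / 2)
  }
})

test_that("normalization modes map ranks to the documented ranges", {
  m <- build_rank_matrix(micro_files())
  frac <- normalize_ranks(m, "fractional")
  expect_equal(frac["b", "PGS1"], 1 / 3)
  expect_true(all(frac > 0 & frac <= 1))
  mm <- normalize_ranks(m, "minmax")
  expect_equal(mm["b", "PGS1"], 0)
  expect_equal(mm["a", "PGS2"], 1)

  single <- build_rank_matrix(list(make_score("P", "rs1", 0.5)))
  expect_equal(as.numeric(normalize_ranks(single, "fractional")), 1)
  expect_equal(as.numeric(normalize_ranks(single, "minmax")), 0)
})

test_that("MRR reproduces hand-computed reciprocals and the micro-example", {
  m <- matrix(c(1, 1, 1), 1, dimnames = list("v", paste0("f", 1:3)))
  class(m) <- c("rank_matrix", class(m))
  expect_equal(unname(mrr_scores(m)), 1)

  m2 <- matrix(c(1, 4), 1, dimnames = list("v", c("f1", "f2")))
  class(m2) <- c("rank_matrix", class(m2))
  expect_equal(unname(mrr_scores(m2)), 0.625)

  mm <- build_rank_matrix(micro_files())
  s <- mrr_scores(mm)
  expect_equal(s[["a"]], 5 / 12)
  expect_equal(s[["b"]], 3 / 4)
  expect_equal(s[["c"]], 2 / 3)
})

test_that("RRA scores match closed-form Beta order-statistic probabilities", {
  r1 <- rra_scores(as_norm_matrix(0.3))
  expect_equal(r1$rho, 0.3)       # Beta(1,1) is Uniform
  expect_equal(r1$corrected, 0.3)

  r3 <- rra_scores(as_norm_matrix(c(0.1, 0.2, 1.0)))
  # p = (1 - 0.9^3, 3*0.2^2 - 2*0.2^3, 1)
  expect_equal(r3$rho, 3 * 0.2^2 - 2 * 0.2^3)
  expect_equal(r3$corrected, 3 * r3$rho)

  worst <- rra_scores(as_norm_matrix(c(1, 1, 1)))
  expect_equal(worst$rho, 1)
  expect_equal(worst$corrected, 1)

  # integer-parameter Beta CDF equals its closed-form polynomial
  set.seed(21)
  for (q in c(2L, 3L, 5L)) {
    r <- sort(runif(q))
    scores <- rra_scores(as_norm_matrix(r))
    p_poly <- vapply(seq_len(q), function(k) {
      j <- k:q
      sum(choose(q, j) * r[k]^j * (1 - r[k])^(q - j))
    }, 1)
    expect_equal(scores$rho, min(p_poly), tolerance = 1e-12)
  }
})

test_that("Stuart scores match closed forms for small Q", {
  expect_equal(unname(stuart_scores(as_norm_matrix(0.4))), 0.4)
  # Q=2, r=(0.5,1): P(min of two uniforms <= 0.5) = 1 - 0.25
  expect_equal(unname(stuart_scores(as_norm_matrix(c(0.5, 1.0)))), 0.75)
  expect_equal(unname(stuart_scores(as_norm_matrix(c(1.0, 1.0)))), 1)
  # Q=2 general closed form: r2^2 - (r2 - r1)^2
  set.seed(5)
  for (i in 1:10) {
    r <- sort(runif(2))
    expect_equal(unname(stuart_scores(as_norm_matrix(r))),
                 r[2]^2 - (r[2] - r[1])^2, tolerance = 1e-12)
  }
  # large Q stays finite and in [0, 1]
  big <- as_norm_matrix(sort(runif(200)))
  q <- unname(stuart_scores(big))
  expect_true(is.finite(q) && q >= 0 && q <= 1)
})

test_that("Borda min, geometric and arithmetic means follow their formulas", {
  expect_equal(unname(borda_scores(as_norm_matrix(c(0.2, 0.8)), "min")), 0.2)
  expect_equal(unname(borda_scores(as_norm_matrix(c(0.25, 0.04)), "geom")), 0.1)
  expect_equal(unname(borda_scores(as_norm_matrix(c(0.2, 0.8)), "mean")), 0.5)
  # a zero rank (minmax mode) gives geometric mean 0, not NaN
  nm <- as_norm_matrix(c(0, 0.5))
  expect_equal(unname(borda_scores(nm, "geom")), 0)
})

test_that("aggregation reproduces the micro-example order and handles one file", {
  agg <- aggregate_ranks(micro_files())
  expect_identical(agg$scores$rsid[order(agg$ranks$dowdall)],
                   c("b", "c", "a"))
  for (method in ra_methods()) {
    expect_true(setequal(agg$ranks[[method]], 1:3))  # permutation of 1..N
  }

  one <- aggregate_ranks(micro_files()[1], methods = c("dowdall", "stuart"))
  expect_identical(one$scores$rsid[order(one$ranks$dowdall)], c("b", "a"))
  expect_identical(one$scores$rsid[order(one$ranks$stuart)], c("b", "a"))

  expect_error(aggregate_ranks(list()), "eligible")
  expect_error(aggregate_ranks(micro_files(), methods = "notamethod"),
               "notamethod")
})

test_that("aggregation is invariant to file order and row order", {
  set.seed(9)
  files <- lapply(1:5, function(j) {
    k <- sample(4:12, 1)
    make_score(sprintf("P%d", j), sample(paste0("rs", 1:20), k), rnorm(k))
  })
  ref <- aggregate_ranks(files)
  perm <- aggregate_ranks(rev(files))
  expect_equal(perm$scores, ref$scores)
  expect_equal(perm$ranks, ref$ranks)

  shuffled <- lapply(files, function(f) {
    f$variants <- f$variants[sample.int(nrow(f$variants)), , drop = FALSE]
    f
  })
  shuf <- aggregate_ranks(shuffled)
  expect_equal(shuf$scores, ref$scores)
  expect_equal(shuf$ranks, ref$ranks)
})

test_that("improving one rank never worsens any method's consensus score", {
  set.seed(33)
  for (rep in 1:20) {
    q <- sample(2:6, 1)
    n <- 30
    ranks <- sort(sample.int(n, q, replace = TRUE))
    j <- sample.int(q, 1)
    if (ranks[j] == 1) next
    improved <- ranks
    improved[j] <- improved[j] - sample.int(improved[j] - 1L, 1L)

    mk <- function(r) {
      m <- matrix(r, 1, dimnames = list("v", paste0("f", seq_len(q))))
      class(m) <- c("rank_matrix", class(m))
      m
    }
    expect_gte(mrr_scores(mk(improved))[["v"]], mrr_scores(mk(ranks))[["v"]])
    nm0 <- as_norm_matrix(ranks / n)
    nm1 <- as_norm_matrix(improved / n)
    expect_lte(rra_scores(nm1)$rho, rra_scores(nm0)$rho)
    expect_lte(unname(stuart_scores(nm1)), unname(stuart_scores(nm0)))
    for (mode in c("min", "geom", "mean")) {
      expect_lte(unname(borda_scores(nm1, mode)),
                 unname(borda_scores(nm0, mode)))
    }
  }
})

test_that("column-wise dominance is preserved by every aggregated ranking", {
  set.seed(77)
  for (rep in 1:10) {
    q <- sample(2:5, 1)
    files <- lapply(seq_len(q), function(j) {
      k <- sample(5:15, 1)
      make_score(sprintf("P%d", j), sample(paste0("rs", 1:25), k),
                 rnorm(k, sd = 2))
    })
    agg <- aggregate_ranks(files)
    m <- agg$rank_matrix
    rsids <- rownames(m)
    for (method in ra_methods()) {
      s <- stats::setNames(agg$scores[[method]], agg$scores$rsid)
      better <- if (method == "dowdall") `>=` else `<=`
      for (i in seq_along(rsids)) {
        # variants whose rank is >= variant i's in every column
        dominated <- which(colSums(t(m) >= m[i, ]) == ncol(m))
        # a dominating variant's consensus score is never worse
        expect_true(all(better(s[rsids[i]], s[rsids[dominated]])))
      }
    }
  }
})

test_that("a variant missing everywhere scores MRR 1/N and worst elsewhere", {
  # extend a one-file universe: rs_ghost appears only via a second file,
  # then check its column in the two-file matrix is all-N where absent
  f1 <- make_score("P1", c("rs1", "rs2", "rs3"), c(3, 2, 1))
  f2 <- make_score("P2", "rs_ghost", 1)
  agg <- aggregate_ranks(list(f1, f2))
  m <- agg$rank_matrix
  n <- nrow(m)
  expect_equal(m["rs_ghost", "P1"], n)
  # rs1..rs3 are missing from P2 and carry rank N there
  expect_equal(unname(m[c("rs1", "rs2", "rs3"), "P2"]), rep(n, 3))
  # a variant ranked worst-or-missing everywhere has MRR 1/N
  worst <- matrix(n, 1, 2, dimnames = list("v", c("a", "b")))
  class(worst) <- c("rank_matrix", class(worst))
  expect_equal(unname(mrr_scores(worst)), 1 / n)
  # and the worst possible score under every other method
  nm_worst <- as_norm_matrix(c(1, 1))
  expect_equal(rra_scores(nm_worst)$rho, 1)
  expect_equal(unname(stuart_scores(nm_worst)), 1)
  for (mode in c("min", "geom", "mean")) {
    expect_equal(unname(borda_scores(nm_worst, mode)), 1)
  }
})

test_that("MRR is bounded by 1/N and 1 with equality only for all-first ranks", {
  set.seed(55)
  n <- 40
  for (rep in 1:20) {
    q <- sample(2:8, 1)
    m <- matrix(replicate(q, sample.int(n)), n,
                dimnames = list(paste0("rs", 1:n), paste0("f", 1:q)))
    class(m) <- c("rank_matrix", class(m))
    s <- mrr_scores(m)
    expect_true(all(s >= 1 / n & s <= 1))
    expect_identical(unname(s == 1), unname(rowSums(m == 1) == q))
  }
})
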