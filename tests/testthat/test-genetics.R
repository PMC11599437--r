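test_that("q-matrix CSV reading validates and renormalizes", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("fish_id,q1,q2,q3,q4",
               "A,0.7,0.2,0.05,0.05",
               "B,0.2501,0.2501,0.2499,0.2499",
               "C,1,0,0,0"), f)
  q <- read_q_matrix(f)
  expect_equal(nrow(q), 3)
  expect_equal(rowSums(q[, 2:5]), rep(1, 3), tolerance = 1e-12,
               ignore_attr = TRUE)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("fish_id,q1,q2,q3,q4", "A,0.5,0.2,0.1,0.1"), bad)
  expect_error(read_q_matrix(bad), "0.9000.*'A'")
  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("fish_id,q1,q2,q3,q4", "A,1,0,0,0", "A,0,1,0,0"), dup)
  expect_error(read_q_matrix(dup), "duplicate")
  neg <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("fish_id,q1,q2,q3,q4", "A,1.2,-0.2,0,0"), neg)
  expect_error(read_q_matrix(neg), "negative")
})

test_that("STRUCTURE-style output parses to the same matrix as CSV", {
  fcsv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("fish_id,q1,q2,q3,q4",
               "F001,0.910,0.050,0.020,0.020",
               "F002,0.100,0.800,0.050,0.050",
               "F003,0.250,0.250,0.250,0.250"), fcsv)
  fstr <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Inferred ancestry of individuals:",
               "    Label (%Miss) Pop:  Inferred clusters",
               "  1 F001    (0)    1 :  0.910 0.050 0.020 0.020",
               "  2 F002    (0)    1 :  0.100 0.800 0.050 0.050",
               "  3 F003    (0)    2 :  0.250 0.250 0.250 0.250",
               ""), fstr)
  a <- read_q_matrix(fcsv, "csv")
  b <- read_q_matrix(fstr, "structure_outfile")
  expect_equal(a, b, ignore_attr = TRUE)
})

test_that("threshold assignment is argmax-above-tau with inclusive boundary", {
  q <- data.frame(fish_id = c("A", "B", "C"),
                  q1 = c(0.8, 0.6, 0.7), q2 = c(0.1, 0.3, 0.3),
                  q3 = c(0.05, 0.05, 0), q4 = c(0.05, 0.05, 0))
  got <- threshold_assign(q, tau = 0.7)
  expect_equal(unname(got), c("q1", "UNASSIGNED", "q1"))
  expect_equal(names(got), c("A", "B", "C"))
  expect_error(threshold_assign(q, tau = 0.5), "tau")
  expect_error(threshold_assign(q, tau = 0.4), "tau")
  # tau > 0.5 means at most one cluster can qualify, ever
  set.seed(61)
  qr <- matrix(rgamma(400, 1), 100, 4)
  qr <- qr / rowSums(qr)
  qd <- data.frame(fish_id = seq_len(100), q1 = qr[, 1], q2 = qr[, 2],
                   q3 = qr[, 3], q4 = qr[, 4])
  lab <- threshold_assign(qd, 0.51)
  hits <- rowSums(qr >= 0.51)
  expect_true(all(hits <= 1))
  expect_equal(sum(lab != "UNASSIGNED"), sum(hits))
})

test_that("univariate pseudo-F equals the classical ANOVA F exactly", {
  set.seed(62)
  y <- c(rnorm(8, 0), rnorm(8, 1), rnorm(8, 3))
  g <- rep(c("a", "b", "c"), each = 8)
  pm <- permanova(matrix(y, ncol = 1), g, n_perm = 99, seed = 1)
  ref <- summary(aov(y ~ g))[[1]]
  expect_equal(pm$pseudo_F, ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(pm$r_squared,
               ref[["Sum Sq"]][1] / sum(ref[["Sum Sq"]]), tolerance = 1e-10)
  # decomposition identity
  expect_equal(pm$r_squared + pm$ss[["within"]] / pm$ss[["total"]], 1,
               tolerance = 1e-10)
})

test_that("multivariate pseudo-F and R2 match the reference implementation", {
  set.seed(63)
  Y <- rbind(matrix(rnorm(40, 0), 10, 4), matrix(rnorm(40, 0.8), 10, 4))
  g <- rep(c("a", "b"), each = 10)
  pm <- permanova(Y, g, n_perm = 999, seed = 2)
  ref <- vegan::adonis2(dist(Y) ~ g, permutations = 999)
  expect_equal(pm$pseudo_F, ref$F[1], tolerance = 1e-10)
  expect_equal(pm$r_squared, ref$R2[1], tolerance = 1e-10)
  expect_lt(abs(pm$p_value - ref$`Pr(>F)`[1]), 0.05)
})

test_that("permanova is invariant to row order and respects input contracts", {
  set.seed(64)
  Y <- matrix(rnorm(60), 20, 3)
  g <- rep(c("a", "b"), each = 10)
  pm1 <- permanova(Y, g, n_perm = 199, seed = 9)
  o <- sample(20)
  pm2 <- permanova(Y[o, ], g[o], n_perm = 199, seed = 9)
  expect_equal(pm1$pseudo_F, pm2$pseudo_F, tolerance = 1e-12)
  expect_equal(pm1$p_value, pm2$p_value)
  expect_error(permanova(Y, rep("a", 20), n_perm = 9), "groups")
  expect_error(permanova(Y, c("b", rep("a", 19)), n_perm = 9), "< 2 members")
  # identical groups duplicated: F near zero, p near 1
  Yd <- rbind(Y[1:10, ], Y[1:10, ])
  pmd <- permanova(Yd, g, n_perm = 199, seed = 3)
  expect_lt(pmd$pseudo_F, 0.05)
  expect_gt(pmd$p_value, 0.9)
})

test_that("pairwise permanova applies BH adjustment over pairs", {
  set.seed(65)
  Y <- rbind(matrix(rnorm(40, 0), 10, 4), matrix(rnorm(40, 0), 10, 4),
             matrix(rnorm(40, 3), 10, 4))
  g <- rep(c("a", "b", "c"), each = 10)
  pw <- pairwise_permanova(Y, g, n_perm = 999, seed = 4)
  expect_equal(nrow(pw), 3)
  expect_equal(pw$p_adjusted, p.adjust(pw$p_value, "BH"))
  # the shifted group separates from both others; a-b does not
  expect_true(all(pw$significant[pw$group_b == "c" | pw$group_a == "c"]))
  expect_false(pw$significant[pw$group_a == "a" & pw$group_b == "b"])
  # BH with all raw p equal leaves them unchanged
  expect_equal(p.adjust(rep(0.04, 3), "BH"), rep(0.04, 3))
})

test_that("ecotype inference is the component closure of non-significant pairs", {
  pairs <- data.frame(
    group_a = c("FW", "FW", "FW", "AN", "AN", "BR"),
    group_b = c("AN", "BR", "CH", "BR", "CH", "CH"),
    p_adjusted = c(0.20, 0.001, 0.001, 0.001, 0.001, 0.001))
  eco <- infer_ecotypes(pairs, c("FW", "AN", "BR", "CH"), alpha = 0.05)
  expect_length(eco$blocks, 3)
  expect_setequal(eco$blocks[[eco$ecotypes[["FW"]]]], c("FW", "AN"))
  # all pairs significant: four singletons
  p2 <- transform(pairs, p_adjusted = 0.001)
  expect_length(infer_ecotypes(p2, c("FW", "AN", "BR", "CH"))$blocks, 4)
  # no pair significant: one ecotype
  p3 <- transform(pairs, p_adjusted = 0.5)
  eco3 <- infer_ecotypes(p3, c("FW", "AN", "BR", "CH"))
  expect_length(eco3$blocks, 1)
  # partition property: blocks disjoint, union is all phenotypes
  expect_setequal(unlist(eco$blocks), c("FW", "AN", "BR", "CH"))
  expect_equal(anyDuplicated(unlist(eco$blocks)), 0)
  expect_error(infer_ecotypes(pairs[-1, ], c("FW", "AN", "BR", "CH")),
               "missing pair")
})

test_that("genotype-location association is tested and guarded", {
  set.seed(66)
  loc <- rep(c("L1", "L2"), each = 40)
  geno <- ifelse(loc == "L1", "G1", "G2")
  flip <- sample(80, 6)
  geno[flip] <- ifelse(geno[flip] == "G1", "G2", "G1")
  r <- genotype_location_test(geno, loc)
  expect_lt(r$p_value, 1e-6)
  expect_error(genotype_location_test(geno, rep("L1", 80)), "single location")
  # unassigned fish are excluded by default
  geno2 <- c(geno, rep("UNASSIGNED", 10))
  loc2 <- c(loc, rep(c("L1", "L2"), 5))
  r2 <- genotype_location_test(geno2, loc2)
  expect_equal(sum(r2$table), 80)
  r3 <- genotype_location_test(geno2, loc2, include_unassigned = TRUE)
  expect_equal(sum(r3$table), 90)
})
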