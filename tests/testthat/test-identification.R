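## the three-equation depression/anxiety/somatic worked example
printed_rows <- c(
  depression = "11110100011000101111",
  anxiety    = "11110100000100011111",
  somatic    = "11110100000011001111")

test_that("the system matrix of the worked example reproduces the printed rows", {
  sm <- build_system_matrix(adolescent_system())
  expect_equal(dim(sm), c(3, 20))
  got <- apply(sm, 1, paste, collapse = "")
  expect_identical(got[names(printed_rows)], printed_rows)
})

test_that("system matrices handle simple and permuted systems", {
  sys1 <- structural_system(endogenous = "y1", exogenous = "x2",
                            equations = list(y1 = "x2"), loop = "y1")
  sm1 <- build_system_matrix(sys1)
  expect_equal(dim(sm1), c(1, 2))
  expect_equal(sm1["y1", c("x2", "y1")], c(x2 = 1L, y1 = 1L))
  ## permuting the declared variable order permutes columns only
  sys <- adolescent_system()
  sys2 <- structural_system(sys$endogenous, rev(sys$exogenous), sys$equations,
                            sys$loop, sys$instruments)
  sm <- build_system_matrix(sys)
  sm2 <- build_system_matrix(sys2)
  expect_identical(sm2[, colnames(sm)], sm)
  expect_error(structural_system("y1", "x1", equations = list(y1 = "zz"),
                                 loop = "y1"), "zz")
  expect_error(structural_system("y1", "x1", equations = list(y1 = c("x1", "y1")),
                                 loop = "y1"), "itself")
})

test_that("order condition counts exclusions against the declared roster", {
  ## an equation containing every variable fails for m >= 2
  sys <- structural_system(c("y1", "y2"), c("x1", "x2"),
                           equations = list(y1 = c("y2", "x1", "x2"),
                                            y2 = c("y1", "x1")),
                           loop = c("y1", "y2"))
  oc <- order_condition(sys)
  expect_false(oc$pass[oc$equation == "y1"])     # zero exclusions
  expect_true(oc$pass[oc$equation == "y2"])      # one exclusion, m - 1 = 1
  ## boundary: m = 3, exactly 2 excluded variables passes
  sys3 <- structural_system(c("y1", "y2", "y3"), c("x1", "x2"),
    equations = list(y1 = c("y2", "y3"), y2 = c("y1", "y3", "x1"),
                     y3 = c("y1", "y2", "x2")),
    loop = c("y1", "y2", "y3"))
  oc3 <- order_condition(sys3)
  expect_equal(oc3$excluded[oc3$equation == "y1"], 2L)
  expect_true(oc3$pass[oc3$equation == "y1"])
  ## m = 2 recursive chain with one exclusion each passes
  chain <- structural_system(c("y1", "y2"), c("x1", "x2"),
                             equations = list(y1 = "x1", y2 = c("y1", "x2")),
                             loop = c("y1", "y2"))
  expect_true(all(order_condition(chain)$pass))
  ## brute-force check of the inequality on the worked example
  sm <- build_system_matrix(adolescent_system())
  expect_equal(order_condition(adolescent_system())$excluded,
               as.integer(rowSums(sm == 0)))
})

test_that("rank condition reduces and ranks exactly as the algorithm states", {
  sys <- adolescent_system()
  rk <- rank_condition(sys)
  expect_equal(rk$rank, c(2L, 2L, 2L))           # rank two for each equation
  expect_true(all(rk$pass))
  expect_true(check_identification(sys)$identified)
  ## all-ones matrix: reduction empties the matrix, rank 0, fail
  ones <- matrix(1L, 3, 5, dimnames = list(paste0("y", 1:3), NULL))
  rk1 <- rank_condition(ones)
  expect_equal(rk1$rank, c(0L, 0L, 0L))
  expect_false(any(rk1$pass))
  expect_error(rank_condition(matrix(nrow = 0, ncol = 0)), "empty")
})

test_that("rank condition agrees with an SVD-rank oracle on random systems", {
  set.seed(11)
  for (r in 1:50) {
    m <- sample(2:4, 1)
    sm <- random_system_matrix(m, sample(3:8, 1))
    rk <- rank_condition(sm)
    oracle <- vapply(seq_len(m), function(i) svd_rank(reduce_system(sm, i)), 0L)
    expect_equal(rk$rank, oracle)
    ## necessity: order-condition failure implies rank-condition failure
    excluded <- rowSums(sm == 0L)
    expect_true(all(rk$pass[excluded < m - 1] == FALSE))
  }
})

test_that("unique-instrument checks pass the worked example and catch misuse", {
  sys <- adolescent_system()
  ui <- check_unique_instruments(sys)
  expect_true(all(ui$pass))
  ## a single instrument shared by both loop variables is not unique: fail
  shared <- structural_system(c("y1", "y2"), c("x1", "x2"),
    equations = list(y1 = c("y2", "x1", "x2"), y2 = c("y1", "x1", "x2")),
    loop = c("y1", "y2"),
    instruments = list(y1 = "x1", y2 = "x1"))
  expect_false(any(check_unique_instruments(shared)$pass))
  ## a uniquely assigned instrument leaking into the other loop equation errors
  leak <- structural_system(c("y1", "y2"), c("x1", "x2"),
    equations = list(y1 = c("y2", "x1"), y2 = c("y1", "x1", "x2")),
    loop = c("y1", "y2"),
    instruments = list(y1 = "x1", y2 = "x2"))
  expect_error(check_unique_instruments(leak), "also appears")
  ## instrument not entering its own equation is an invalid assignment
  bad <- structural_system(c("y1", "y2"), c("x1", "x2"),
    equations = list(y1 = c("y2", "x1"), y2 = c("y1", "x2")),
    loop = c("y1", "y2"), instruments = list(y1 = "x2", y2 = "x2"))
  expect_error(check_unique_instruments(bad), "does not enter")
})

test_that("deleting a non-recursive path never decreases exclusion counts", {
  sys <- adolescent_system()
  before <- order_condition(sys)$excluded
  sys$equations$depression <- setdiff(sys$equations$depression, "somatic")
  sys$equations$anxiety <- setdiff(sys$equations$anxiety, "somatic")
  after <- order_condition(sys)$excluded
  expect_true(all(after >= before))
})
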