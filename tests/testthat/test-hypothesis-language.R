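nm4 <- c("b0", "b1", "b2", "b3")

test_that("order chains produce the difference-form inequality matrix", {
  sys <- parse_hypotheses("b1 > b2 > b3 > 0", nm4)[[1]]
  expect_equal(sys$R_I,
               rbind(c(0, 1, -1, 0), c(0, 0, 1, -1), c(0, 0, 0, 1)))
  expect_equal(sys$r_I, c(0, 0, 0))
  expect_equal(nrow(sys$R_E), 0L)
})

test_that("equality chains split into adjacent equality rows plus the trailing inequality", {
  sys <- parse_hypotheses("b1 = b2 = b3 > 0", nm4)[[1]]
  expect_equal(sys$R_E, rbind(c(0, 1, -1, 0), c(0, 0, 1, -1)))
  expect_equal(sys$r_E, c(0, 0))
  expect_equal(sys$R_I, rbind(c(0, 0, 0, 1)))
  expect_equal(sys$r_I, 0)
})

test_that("groups expand one row per member and keep redundant inequalities", {
  nms <- c("(Intercept)", "beliefW", "stigma", "feminist")
  sys <- parse_hypotheses("beliefW > (stigma, feminist) = 0", nms)[[1]]
  expect_equal(sys$R_E, rbind(c(0, 0, 1, 0), c(0, 0, 0, 1)))
  expect_equal(sys$r_E, c(0, 0))
  # redundant rows are kept; rank handling downstream routes them to MC
  expect_equal(sys$R_I, rbind(c(0, 1, -1, 0), c(0, 1, 0, -1)))
  expect_equal(sys$r_I, c(0, 0))
})

test_that("mirrored comparisons and whitespace do not change the parse", {
  a <- parse_hypotheses("b1 < b2", nm4)[[1]]
  b <- parse_hypotheses("b2 > b1", nm4)[[1]]
  expect_equal(a$R_I, b$R_I)
  expect_equal(a$r_I, b$r_I)
  c1 <- parse_hypotheses("b1>b2>b3>0", nm4)[[1]]
  c2 <- parse_hypotheses("  b1 >  b2\t> b3 > 0 ", nm4)[[1]]
  expect_equal(c1$R_I, c2$R_I)
})

test_that("nonzero constants, name differences and the intercept are handled", {
  sys <- parse_hypotheses("b1 - b2 > 0.2", nm4)[[1]]
  expect_equal(sys$R_I, rbind(c(0, 1, -1, 0)))
  expect_equal(sys$r_I, 0.2)
  sys2 <- parse_hypotheses("b1 > -0.5", nm4)[[1]]
  expect_equal(sys2$r_I, -0.5)
  nms <- c("(Intercept)", "x1")
  sys3 <- parse_hypotheses("(Intercept) = 0", nms)[[1]]
  expect_equal(sys3$R_E, rbind(c(1, 0)))
})

test_that("parse errors are informative", {
  expect_error(parse_hypotheses("b9 > 0", nm4), "unknown coefficient 'b9'.*b0")
  expect_error(parse_hypotheses("b1", nm4), "no comparator")
  expect_error(parse_hypotheses("(b1, > 0", nm4), "malformed group")
  expect_error(parse_hypotheses("b1 > b2 = b1", nm4), "infeasible")
  expect_error(parse_hypotheses("b1 > b1", nm4), "nfeasible")
})

test_that("redundant equality rows are dropped; inconsistent ones rejected", {
  sys <- parse_hypotheses("b1 = b2 & b2 = b1 & b3 = 0", nm4)[[1]]
  expect_equal(nrow(sys$R_E), 2L)
  expect_error(parse_hypotheses("b1 = 0 & b1 = 1", nm4), "nfeasible|nconsistent")
})

test_that("feasibility check returns strict witnesses", {
  sys <- parse_hypotheses("b1 > b2 > b3 > 0", nm4)[[1]]
  feas <- check_feasibility(sys)
  expect_true(feas$feasible)
  w <- feas$witness
  expect_true(all(sys$R_I %*% w > sys$r_I))
  sys2 <- parse_hypotheses("b1 = b2 = b3 > 0", nm4)[[1]]
  w2 <- check_feasibility(sys2)$witness
  expect_equal(max(abs(sys2$R_E %*% w2 - sys2$r_E)), 0, tolerance = 1e-8)
  expect_true(all(sys2$R_I %*% w2 > sys2$r_I))
  # bounded slack region 0 < b1 < 0.05 still feasible
  sys3 <- parse_hypotheses("0 < b1 < 0.05", nm4)[[1]]
  expect_true(check_feasibility(sys3)$feasible)
})

test_that("exploratory triples partition the line for any coefficient", {
  for (nm in c("b1", "b0")) {
    triple <- exploratory_hypotheses(nm, nm4)
    expect_length(triple, 3L)
    expect_true(attr(triple, "exhaustive"))
    j <- match(nm, nm4)
    expect_equal(triple[[1]]$R_I[1, j], -1)
    expect_equal(triple[[2]]$R_E[1, j], 1)
    expect_equal(triple[[3]]$R_I[1, j], 1)
    # regions cover every real value of the tested coefficient exactly once
    for (v in c(-2, 0, 1.5)) {
      beta <- numeric(4); beta[j] <- v
      inside <- vapply(triple, function(s) {
        okE <- !nrow(s$R_E) || all(abs(s$R_E %*% beta - s$r_E) < 1e-12)
        okI <- !nrow(s$R_I) || all(s$R_I %*% beta > s$r_I)
        okE && okI
      }, logical(1))
      expect_equal(sum(inside), 1L)
    }
  }
  expect_error(exploratory_hypotheses("zz", nm4), "unknown coefficient")
})

test_that("canonical rendering round-trips to the same matrices", {
  specs <- c("b1 > b2 > b3 > 0", "b1 = b2 = b3 > 0",
             "b1 > (b2, b3) = 0", "b1 - b2 > 0.2 & b3 < 0.5")
  for (s in specs) {
    sys <- parse_hypotheses(s, nm4)[[1]]
    back <- parse_hypotheses(format(sys), nm4)[[1]]
    expect_equal(back$R_E, sys$R_E, info = s)
    expect_equal(back$r_E, sys$r_E, info = s)
    expect_equal(back$R_I, sys$R_I, info = s)
    expect_equal(back$r_I, sys$r_I, info = s)
  }
})

test_that("grouped and chained zero-equality forms define the same feasible set", {
  nms <- c("(Intercept)", "beliefW", "stigma", "feminist")
  a <- parse_hypotheses("beliefW > (stigma, feminist) = 0", nms)[[1]]
  b <- parse_hypotheses("beliefW > stigma = feminist = 0", nms)[[1]]
  set.seed(42)
  member <- function(sys, beta) {
    okE <- all(abs(sys$R_E %*% beta - sys$r_E) < 1e-9)
    okI <- all(sys$R_I %*% beta > sys$r_I)
    okE && okI
  }
  for (i in 1:200) {
    beta <- rnorm(4, sd = 2)
    if (i %% 3 == 0) beta[3:4] <- 0  # land on the equality set sometimes
    expect_equal(member(a, beta), member(b, beta))
  }
  # and identical transformed inequality geometry after equality reduction
  ta <- transform_system(a); tb <- transform_system(b)
  expect_equal(ta$rank_RtildeI, tb$rank_RtildeI)
})
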