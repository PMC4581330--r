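test_that("zero-parameter networks output the uniform distribution", {
  set.seed(21)
  st <- zeroed_stage(brnn_stage(d = 5, state_width = 3, hidden_width = 3,
                                span = 2))
  X <- matrix(runif(40), 8, 5)
  P <- stage_forward(st, X)
  expect_equal(P, matrix(0.5, 8, 2))

  model <- zeroed_model(two_stage_model(5, filter_geometry(2, 2),
                                        state_width = 3, hidden_width = 3))
  expect_equal(two_stage_predict(model, X), matrix(0.5, 8, 2))

  nn <- nn_baseline(5, window = 3, hidden = 4)
  nn$W1[] <- 0; nn$b1[] <- 0; nn$W2[] <- 0; nn$b2[] <- 0
  expect_equal(nn_baseline_forward(nn, X), matrix(0.5, 8, 2))
})

test_that("single-position forward pass equals a dense two-layer oracle", {
  set.seed(22)
  st <- brnn_stage(d = 4, state_width = 3, hidden_width = 3, span = 1)
  x <- matrix(runif(4), 1, 4)
  # states are zero at the boundaries, so h^F = tanh(WF2 tanh(WF1 [x;0]+b)+b)
  hF <- tanh(st$WF2 %*% tanh(st$WF1 %*% c(x, numeric(3)) + st$bF1) + st$bF2)
  hB <- tanh(st$WB2 %*% tanh(st$WB1 %*% c(x, numeric(3)) + st$bB1) + st$bB2)
  z <- tanh(st$WO1 %*% c(x, hF, hB) + st$bO1)
  logits <- st$WO2 %*% z + st$bO2
  probs <- exp(logits - max(logits)); probs <- probs / sum(probs)
  expect_equal(unname(stage_forward(st, x)[1, ]), as.numeric(probs),
               tolerance = 1e-12)
})

test_that("reversing the sequence and swapping chains reverses the output", {
  set.seed(23)
  st <- brnn_stage(d = 6, state_width = 4, hidden_width = 4, span = 2)
  sw <- st
  sw$WF1 <- st$WB1; sw$bF1 <- st$bB1; sw$WF2 <- st$WB2; sw$bF2 <- st$bB2
  sw$WB1 <- st$WF1; sw$bB1 <- st$bF1; sw$WB2 <- st$WF2; sw$bB2 <- st$bF2
  # output net sees (x, hF, hB): swap its state blocks too
  d <- 6; H <- 4
  sw$WO1 <- cbind(st$WO1[, 1:d], st$WO1[, (d + H + 1):(d + 2 * H)],
                  st$WO1[, (d + 1):(d + H)])
  X <- matrix(runif(60), 10, 6)
  P <- stage_forward(st, X)
  Prev <- stage_forward(sw, X[10:1, ])
  expect_equal(Prev, P[10:1, ], tolerance = 1e-12)
})

test_that("filter inputs handle constant fields and degenerate geometry", {
  n <- 400
  P <- matrix(rep(c(0.3, 0.7), each = n), n, 2)
  g <- filter_geometry(w = 7, p = 10)
  Fm <- build_filter_inputs(P, g)
  expect_equal(ncol(Fm), 2 * (2 * 10 + 2))
  j <- 200                                  # interior: all windows in range
  expect_equal(unname(Fm[j, ]), rep(c(0.3, 0.7), 22), tolerance = 1e-12)

  g0 <- filter_geometry(w = 0, p = 0)
  F0 <- build_filter_inputs(P[1:5, ], g0)
  expect_equal(F0[, 1:2], F0[, 3:4])        # c_j duplicated
})

test_that("filter inputs match the exhaustive double-loop oracle", {
  set.seed(24)
  for (geom in list(c(1, 1), c(0, 2), c(2, 0), c(3, 2))) {
    P <- matrix(runif(20), 10, 2)
    P <- P / rowSums(P)
    g <- filter_geometry(geom[1], geom[2])
    expect_equal(build_filter_inputs(P, g),
                 filter_inputs_oracle(P, geom[1], geom[2]),
                 tolerance = 1e-12)
  }
})

test_that("probability rows sum to one at every stage", {
  set.seed(25)
  model <- two_stage_model(7, filter_geometry(2, 3), state_width = 4,
                          hidden_width = 4, span = 2)
  X <- matrix(rnorm(7 * 30), 30, 7)
  both <- two_stage_predict(model, X, both = TRUE)
  expect_equal(rowSums(both$stage1), rep(1, 30), tolerance = 1e-9)
  expect_equal(rowSums(both$output), rep(1, 30), tolerance = 1e-9)
})

test_that("short chains pass through the full default filter span", {
  set.seed(26)
  model <- two_stage_model(21, filter_geometry(), state_width = 3,
                          hidden_width = 3, span = 2)
  X <- matrix(runif(21 * 5), 5, 21)
  P <- two_stage_predict(model, X)
  expect_equal(dim(P), c(5L, 2L))
  expect_true(all(is.finite(P)))
})

test_that("with zero transition weights outputs are strictly local", {
  set.seed(27)
  st <- brnn_stage(d = 5, state_width = 3, hidden_width = 3, span = 1)
  st$WF1[] <- 0; st$WF2[] <- 0; st$WB1[] <- 0; st$WB2[] <- 0
  X <- matrix(runif(50), 10, 5)
  P <- stage_forward(st, X)
  X2 <- X
  X2[4, ] <- runif(5)                       # perturb one position
  P2 <- stage_forward(st, X2)
  expect_equal(P2[-4, ], P[-4, ], tolerance = 1e-14)
  expect_false(isTRUE(all.equal(P2[4, ], P[4, ])))
})

test_that("analytic gradient matches central finite differences", {
  set.seed(28)
  model <- two_stage_model(4, filter_geometry(1, 1), state_width = 3,
                          hidden_width = 3, span = 2)
  X <- matrix(runif(4 * 10), 10, 4)
  y <- sample(0:1, 10, replace = TRUE)
  g <- two_stage_grad(model, X, y)
  gflat <- unlist(lapply(c("grad1", "grad2"), function(gn)
    unlist(g[[gn]][disbrnn:::STAGE_PAR_NAMES])))
  theta <- flatten_params(model)
  h <- 1e-4
  idx <- sample(seq_along(theta), 60)
  for (k in idx) {
    tp <- theta; tp[k] <- tp[k] + h
    tm <- theta; tm[k] <- tm[k] - h
    num <- (two_stage_loss(unflatten_params(model, tp), X, y) -
            two_stage_loss(unflatten_params(model, tm), X, y)) / (2 * h)
    expect_lt(abs(num - gflat[k]) / max(abs(num), 1e-6), 1e-5)
  }
})

test_that("baseline window network matches a dense oracle at window 1", {
  set.seed(29)
  nn <- nn_baseline(6, window = 1, hidden = 5)
  X <- matrix(runif(60), 10, 6)
  P <- nn_baseline_forward(nn, X)
  for (j in 1:10) {
    z <- tanh(nn$W1 %*% X[j, ] + nn$b1)
    logits <- nn$W2 %*% z + nn$b2
    pr <- exp(logits - max(logits)); pr <- pr / sum(pr)
    expect_equal(unname(P[j, ]), as.numeric(pr), tolerance = 1e-12)
  }
})

test_that("baseline geometry: 21-wide input and window 21 give fan-in 441", {
  nn <- nn_baseline(21, window = 21, hidden = 20)
  expect_identical(ncol(nn$W1), 441L)
  expect_identical(nrow(nn$W1), 20L)
  expect_error(nn_baseline(21, window = 20), "odd")
})

test_that("model serialization round-trips to identical predictions", {
  set.seed(30)
  members <- lapply(1:2, function(i)
    two_stage_model(21, filter_geometry(2, 2), state_width = 3,
                    hidden_width = 3, span = 1))
  ens <- ensemble_model(members)
  X <- matrix(runif(21 * 15), 15, 21)
  p0 <- ensemble_predict(ens, X)
  path <- tempfile(fileext = ".json")
  write_model(ens, path, variant = "MSA", threshold = 0.37)
  back <- read_model(path)
  expect_identical(ensemble_predict(back$ensemble, X), p0)
  expect_identical(back$variant, "MSA")
  expect_identical(back$threshold, 0.37)
  unlink(path)
})
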