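test_that("bound_weight_sum matches hand and brute-force enumeration", {
  m <- toy_scl19()
  # all-zero weights: empty enhancer contributes nothing
  m0 <- enhancer_model("scl19", c(G = 0, FF = 0, G.FF = 0), K = 100)
  expect_identical(bound_weight_sum(m0, triad_state(1, 1, 1)), 0)
  # hand sums (Fli1 enters as a dimer: exponent 2)
  expect_equal(bound_weight_sum(m, c(1, 2, 1)), 2 * 2 + 3 * 1 + 5 * 2 * 1)
  expect_equal(bound_weight_sum(m, c(1, 2, 3)),
               2 * 2 + 3 * 9 + 5 * 2 * 9) # 121, enumeration over 3 configs
  expect_error(bound_weight_sum(m, c(-1, 1, 1)), ">= 0")
})

test_that("fold enhancement is bounded in [1, K) and saturates at K", {
  m0 <- enhancer_model("scl19", c(G = 0, FF = 0, G.FF = 0), K = 50)
  expect_equal(fold_enhancement(m0, triad_state()), 1)
  # saturation: enormous weight drives F to K
  msat <- enhancer_model("scl19", c(G = 1e12, FF = 0, G.FF = 0), K = 1000)
  expect_equal(fold_enhancement(msat, triad_state()), 1000,
               tolerance = 1e-6)
  # randomized sweep: 1 <= F < K, increasing in the weights
  set.seed(42)
  for (i in 1:50) {
    w <- 10^runif(3, -2, 5)
    K <- 10^runif(1, 0.5, 4)
    m <- enhancer_model("scl19", setNames(w, c("G", "FF", "G.FF")), K)
    x <- 10^runif(3, -2, 1)
    f1 <- fold_enhancement(m, x)
    expect_gte(f1, 1)
    expect_lt(f1, K)
    m2 <- enhancer_model("scl19", setNames(w * 2, c("G", "FF", "G.FF")), K)
    expect_gt(fold_enhancement(m2, x), f1)
  }
  expect_error(enhancer_model("scl19", c(G = 1), K = 1), "> 1")
})

test_that("fold enhancement equals the explicit two-level partition function", {
  # oracle: enumerate closed + open(empty/bound) x promoter states with a
  # weak polymerase weight; must agree for random enhancers and states
  set.seed(7)
  for (key in c("scl19", "gata2m3", "fli1p12")) {
    for (i in 1:20) {
      topo <- enhancer_topology(key)
      w <- setNames(10^runif(nrow(topo), -2, 4), topo$id)
      m <- enhancer_model(key, w, K = 10^runif(1, 0.5, 3.5))
      x <- 10^runif(3, -2, 1)
      expect_equal(fold_enhancement(m, x), brute_force_fold(m, x),
                   tolerance = 1e-6)
    }
  }
})

test_that("transcription factor reduces to fold enhancement at zero signal", {
  params <- fixture_params()
  for (m in params$models) {
    f0 <- transcription_factor(m, triad_state(), signal_input())
    expect_equal(f0 * m$K, fold_enhancement(m, triad_state()),
                 tolerance = 1e-12)
  }
})

test_that("eta acts multiplicatively on the Gata2 transcription factor only", {
  params <- fixture_params()
  g <- params$models$gata2m3
  f1 <- transcription_factor(g, triad_state(), signal_input(eta = 1))
  f05 <- transcription_factor(g, triad_state(), signal_input(eta = 0.5))
  expect_equal(f05, f1 / 2, tolerance = 1e-12)
  s <- params$models$scl19
  expect_equal(transcription_factor(s, triad_state(), signal_input(eta = 0.5)),
               transcription_factor(s, triad_state(), signal_input()),
               tolerance = 1e-12)
})

test_that("transcription factor is monotone in TR concentrations and signals", {
  params <- fixture_params()
  set.seed(11)
  for (m in params$models) {
    for (i in 1:20) {
      x <- 10^runif(3, -2, 1)
      sg <- signal_input(n = 10^runif(1, -2, 2), b = 10^runif(1, -2, 2),
                         eta = runif(1, 0.2, 1))
      f0 <- transcription_factor(m, x, sg)
      for (j in 1:3) {
        x2 <- x; x2[j] <- x[j] * 1.05
        expect_gte(transcription_factor(m, x2, sg), f0 - 1e-14)
      }
      expect_gte(transcription_factor(m, x,
                                      signal_input(sg$n, sg$b,
                                                   min(1, sg$eta * 1.2))),
                 f0 - 1e-14)
      # each activation signal is monotone with the other at zero (with
      # both present, promoter competition lets the weaker activator
      # displace the stronger one, so joint monotonicity is not implied)
      fn0 <- transcription_factor(m, x, signal_input(sg$n, 0, sg$eta))
      expect_gte(transcription_factor(m, x,
                                      signal_input(sg$n * 1.5, 0, sg$eta)),
                 fn0 - 1e-14)
      fb0 <- transcription_factor(m, x, signal_input(0, sg$b, sg$eta))
      expect_gte(transcription_factor(m, x,
                                      signal_input(0, sg$b * 1.5, sg$eta)),
                 fb0 - 1e-14)
    }
  }
})

test_that("omega calibration reproduces the saturating fold increases", {
  params <- fixture_params()
  g <- params$models$gata2m3
  f0 <- transcription_factor(g, triad_state(), signal_input())
  # asymptotic ratio, exact form
  Z <- bound_weight_sum(g, triad_state())
  expect_equal(g$omega[["notch"]] * (g$K + Z) / (1 + Z), 3.5,
               tolerance = 1e-6)
  expect_equal(g$omega[["bmp4"]] * (g$K + Z) / (1 + Z), 4,
               tolerance = 1e-6)
  # numerically at n (or b) = 1e6
  expect_equal(transcription_factor(g, triad_state(),
                                    signal_input(n = 1e6)) / f0,
               3.5, tolerance = 1e-3)
  expect_equal(transcription_factor(g, triad_state(),
                                    signal_input(b = 1e6)) / f0,
               4, tolerance = 1e-3)
  # Fli1+12 carries the Bmp4 factor only
  f <- params$models$fli1p12
  ff0 <- transcription_factor(f, triad_state(), signal_input())
  expect_equal(transcription_factor(f, triad_state(),
                                    signal_input(b = 1e6)) / ff0,
               4, tolerance = 1e-3)
  expect_equal(transcription_factor(f, triad_state(),
                                    signal_input(n = 1e6)) / ff0,
               1, tolerance = 1e-12)
})

test_that("a neutral cofactor (fold 1) leaves saturating output unchanged", {
  g <- fit_enhancer(fixture_table(), "gata2m3", K = 525)
  expect_warning(g1 <- calibrate_omegas(g, fold_notch = 1, fold_bmp4 = 4),
                 "repression-like")
  f0 <- transcription_factor(g1, triad_state(), signal_input())
  expect_equal(transcription_factor(g1, triad_state(),
                                    signal_input(n = 1e6)) / f0,
               1, tolerance = 1e-3)
})

test_that("site deletion cascades to every configuration using the site", {
  params <- fixture_params()
  f <- params$models$fli1p12
  # deleting the primary GATA site leaves only the Fli1-dimer state
  fd <- delete_sites(f, "pGATA")
  expect_equal(fd$configurations$weight[fd$configurations$id != "FF"],
               c(0, 0, 0))
  expect_gt(fd$configurations$weight[fd$configurations$id == "FF"], 0)
  # deleting the E-BOX removes only the full complex
  fe <- delete_sites(f, "EBOX")
  expect_equal(fe$configurations$weight[fe$configurations$id == "G.S.FF.G"], 0)
  expect_true(all(fe$configurations$weight[fe$configurations$id !=
                                             "G.S.FF.G"] > 0))
  expect_error(delete_sites(f, "NOPE"), "Unknown site")
})
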