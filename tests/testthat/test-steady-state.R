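test_that("wild-type triad is bistable with a saddle between OFF and ON", {
  params <- fixture_params()
  ss <- find_steady_states(params)
  expect_true(all(ss$residual < 1e-10))
  st <- dplyr::filter(ss, stable)
  expect_equal(nrow(st), 2)
  on <- as.numeric(st[which.max(st$x_g), c("x_s", "x_g", "x_f")])
  off <- as.numeric(st[which.min(st$x_g), c("x_s", "x_g", "x_f")])
  expect_equal(on, c(1, 1, 1), tolerance = 1e-6)
  expect_true(all(off < 0.1))
  # a saddle separates the attractors
  un <- dplyr::filter(ss, !stable)
  expect_gte(nrow(un), 1)
  expect_true(any(un$x_g > off[2] & un$x_g < on[2]))
  # no two reported states within the merge radius
  xs <- as.matrix(ss[, c("x_s", "x_g", "x_f")])
  if (nrow(xs) > 1) {
    for (i in 2:nrow(xs)) for (j in 1:(i - 1)) {
      expect_gt(max(abs(log(xs[i, ] + 1e-8) - log(xs[j, ] + 1e-8))), 1e-4)
    }
  }
})

test_that("Newton-found attractors agree with an integration-only oracle", {
  params <- fixture_params()
  ss <- dplyr::filter(find_steady_states(params), stable)
  att <- basin_attractors(params, n_starts = 20, seed = 4)
  # every attractor reached by integration is a reported stable state
  for (a in att) {
    d <- apply(as.matrix(ss[, c("x_s", "x_g", "x_f")]), 1,
               function(s) max(abs(log(s + 1e-8) - log(a + 1e-8))))
    expect_lt(min(d), 0.05)
  }
  # and every reported stable state is reached from some start
  for (i in seq_len(nrow(ss))) {
    s <- as.numeric(ss[i, c("x_s", "x_g", "x_f")])
    d <- purrr::map_dbl(att, ~ max(abs(log(.x + 1e-8) - log(s + 1e-8))))
    expect_lt(min(d), 0.05)
  }
})

test_that("stability flags match perturbed long-time behavior", {
  params <- fixture_params()
  ss <- find_steady_states(params)
  for (i in seq_len(nrow(ss))) {
    x <- as.numeric(ss[i, c("x_s", "x_g", "x_f")])
    xp <- x * 1.02 + 1e-6
    tr <- integrate_triad(params, xp, signal_input(), horizon = 120)
    xe <- as.numeric(utils::tail(tr, 1)[, c("x_s", "x_g", "x_f")])
    returned <- max(abs(log(xe + 1e-8) - log(x + 1e-8))) < 0.02
    expect_equal(returned, ss$stable[i])
  }
})

test_that("knockouts are monostable low", {
  params <- fixture_params()
  for (g in c("Scl", "Gata2", "Fli1")) {
    ko <- make_design(params, paste0("ko:", g))
    ss <- find_steady_states(ko)
    st <- dplyr::filter(ss, stable)
    expect_equal(nrow(st), 1)
    expect_lt(st$x_g, 0.1)
  }
})

test_that("wild-type response is irreversibly bistable on each signal axis", {
  params <- fixture_params()
  grid_nb <- c(0, 10^seq(-2, 3, length.out = 11))
  for (ax in c("notch", "bmp4")) {
    rc <- trace_response(params, ax, grid = grid_nb)
    expect_equal(rc$classification, "irreversible_bistable")
    expect_gte(length(rc$thresholds), 1)
    # ON branch exists at zero signal after switching
    s0 <- dplyr::filter(rc$curve, signal == 0, stable)
    expect_gte(nrow(s0), 2)
  }
  rc_e <- trace_response(params, "eta",
                         grid = exp(seq(log(1), log(0.01), length.out = 11)))
  expect_equal(rc_e$classification, "irreversible_bistable")
})

test_that("hysteresis: quasi-static up-down sweep strands the system ON", {
  params <- fixture_params()
  oo <- triadswitch:::off_on_states(params)
  x <- oo$off
  thr <- max(trace_response(params, "notch",
                            grid = c(0, 10^seq(-1, 2, length.out = 8)))$thresholds)
  up <- c(10^seq(-1, log10(thr * 3), length.out = 8))
  for (n in c(up, rev(up), 0)) {
    tr <- integrate_triad(params, x, signal_input(n = n), horizon = 50)
    x <- as.numeric(utils::tail(tr, 1)[, c("x_s", "x_g", "x_f")])
  }
  expect_lt(max(abs(log(x + 1e-8) - log(oo$on + 1e-8))), 0.05)
})

test_that("Fli1+12 site deletions leave a signal-inducible high state", {
  params <- fixture_params()
  grid <- c(0, 10^seq(-2, 3, length.out = 21))
  # Scl-site (E-BOX) and Fli1-site (ETS) deletions: reversible bistability
  for (d in c("fli1p12:dEBOX", "fli1p12:dETS", "fli1p12:dsGATA")) {
    rc <- trace_response(make_design(params, d), "notch", grid = grid)
    expect_equal(rc$classification, "reversible_bistable")
  }
  # primary-GATA deletion decouples Fli1 from Notch entirely
  pdg <- make_design(params, "fli1p12:dpGATA")
  rc <- trace_response(pdg, "notch", grid = c(0, 1, 10, 100))
  xf_by_signal <- dplyr::summarize(
    dplyr::group_by(dplyr::filter(rc$curve, stable), signal),
    xf = min(x_f))
  expect_lt(diff(range(xf_by_signal$xf)), 1e-6)
})

test_that("the switchability scan refits and classifies each grid point", {
  tb <- fixture_table()
  res <- suppressWarnings(
    switchability_scan(tb, K_s = 862, K_g_grid = c(525, 5000),
                       K_f_grid = c(63, 5000)))
  expect_equal(nrow(res), 4)
  # just above the feasibility bounds both signals switch the triad
  near <- dplyr::filter(res, K_g == 525, K_f == 63)
  expect_equal(near$outcome, "both_switch")
  expect_true(all(res$outcome != "infeasible"))
  # infeasible K values are flagged, not fit
  res2 <- switchability_scan(tb, K_s = 862, K_g_grid = 100, K_f_grid = 63)
  expect_equal(res2$outcome, "infeasible")
})

test_that("with energies fixed, switchable bistability is robust to K changes", {
  params <- fixture_params()
  scaled <- purrr::map(params$models, function(m) {
    w <- setNames(m$configurations$weight, m$configurations$id)
    enhancer_model(m$key, w, m$K * 3, omega = m$omega)
  })
  p3 <- triad_parameters(scaled$scl19, scaled$gata2m3, scaled$fli1p12)
  oo <- triadswitch:::off_on_states(p3)
  expect_true(triadswitch:::sustained_switches(p3, "notch", 1e3, oo$off, oo$on))
  expect_true(triadswitch:::sustained_switches(p3, "bmp4", 1e3, oo$off, oo$on))
})
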