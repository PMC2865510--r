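test_that("invert_single solves the fold equation exactly", {
  expect_identical(invert_single(1, 900), 0)
  # independent oracle: numeric root of K(1+w)/(K+w) = F
  oracle <- uniroot(function(w) 900 * (1 + w) / (900 + w) - 820.51,
                    c(0, 1e9), tol = 1e-9)$root
  expect_equal(invert_single(820.51, 900), oracle, tolerance = 1e-8)
  expect_equal(invert_single(820.51, 900), 9278.64, tolerance = 1e-5)
  # round trip through the forward formula
  set.seed(3)
  for (i in 1:30) {
    K <- 10^runif(1, 0.5, 4)
    w <- 10^runif(1, -3, 6)
    F <- K * (1 + w) / (K + w)
    expect_equal(invert_single(F, K), w, tolerance = 1e-9)
  }
  expect_error(invert_single(820.51, 800), "maximal possible enhancement",
               class = "triadswitch_infeasible")
  expect_error(invert_single(0.5, 900), class = "triadswitch_data_error")
})

test_that("feasibility bound is the largest measured enhancement", {
  tb <- fixture_table()
  expect_equal(feasibility_bound(dplyr::filter(tb, enhancer == "Scl+19")),
               820.51)
  expect_equal(feasibility_bound(dplyr::filter(tb, enhancer == "Fli1+12")),
               60)
  ones <- tibble::tibble(enhancer = "Scl+19", construct = "x",
                         intact_sites = "GATA", fold_enhancement = 1)
  expect_equal(feasibility_bound(ones), 1)
})

test_that("Scl+19 fit reproduces every measured fold exactly", {
  tb <- fixture_table()
  m <- fit_enhancer(tb, "scl19", K = 900)
  expect_equal(fold_enhancement(m, triad_state()), 820.51,
               tolerance = 1e-12)
  expect_equal(fold_enhancement(delete_sites(m, "ETS"), triad_state()),
               40, tolerance = 1e-12)
  expect_equal(fold_enhancement(delete_sites(m, "GATA"), triad_state()),
               60, tolerance = 1e-12)
  # infeasible K rejects with the bound named
  expect_error(fit_enhancer(tb, "scl19", K = 800), "820.51",
               class = "triadswitch_infeasible")
  # negative composite weight aborts rather than clamping
  bad <- tibble::tibble(
    enhancer = "Scl+19", construct = c("g", "ff", "wt"),
    intact_sites = c("GATA", "ETS", "GATA;ETS"),
    fold_enhancement = c(40, 60, 90))
  expect_error(fit_enhancer(bad, "scl19", K = 1000), "negative weight",
               class = "triadswitch_infeasible")
  # all-ones table: no binding anywhere
  flat <- tibble::tibble(
    enhancer = "Scl+19", construct = c("g", "ff", "wt"),
    intact_sites = c("GATA", "ETS", "GATA;ETS"),
    fold_enhancement = c(1, 1, 1))
  expect_equal(fit_enhancer(flat, "scl19", K = 10)$configurations$weight,
               c(0, 0, 0))
})

test_that("Gata2-3 fit handles the Scl-site recursion", {
  tb <- fixture_table()
  m <- fit_enhancer(tb, "gata2m3", K = 600)
  for (row in list(list(s = "GATA", f = 15), list(s = "ETS", f = 25),
                   list(s = c("GATA", "ETS"), f = 150),
                   list(s = c("GATA", "ETS", "EBOX"), f = 500))) {
    dm <- delete_sites(m, setdiff(enhancer_sites("gata2m3"), row$s))
    expect_equal(fold_enhancement(dm, triad_state()), row$f,
                 tolerance = 1e-12)
  }
  # an Scl-site-only construct has no surviving configuration
  only_ebox <- delete_sites(m, c("GATA", "ETS"))
  expect_equal(fold_enhancement(only_ebox, triad_state()), 1)
  # identical full and EBOX-deleted folds imply a zero complex weight
  same <- tibble::tibble(
    enhancer = "Gata2-3", construct = c("g", "ff", "de", "wt"),
    intact_sites = c("GATA", "ETS", "GATA;ETS", "GATA;ETS;EBOX"),
    fold_enhancement = c(15, 25, 150, 150))
  ms <- fit_enhancer(same, "gata2m3", K = 600)
  expect_equal(ms$configurations$weight[ms$configurations$id == "S.G.FF"], 0,
               tolerance = 1e-9)
})

test_that("Fli1+12 fit reproduces the 20x and 60x anchors", {
  tb <- fixture_table()
  m <- fit_enhancer(tb, "fli1p12", K = 63)
  expect_equal(fold_enhancement(m, triad_state()), 60, tolerance = 1e-12)
  # double mutant (Scl site and secondary GATA deleted) drops to 20
  dm <- delete_sites(m, c("EBOX", "sGATA"))
  expect_equal(fold_enhancement(dm, triad_state()), 20, tolerance = 1e-12)
  # Scl-site-only and secondary-GATA-only constructs cannot enhance
  expect_equal(fold_enhancement(delete_sites(m, c("pGATA", "ETS", "sGATA")),
                                triad_state()), 1)
  expect_equal(fold_enhancement(delete_sites(m, c("pGATA", "ETS", "EBOX")),
                                triad_state()), 1)
})

test_that("noise-free synthetic tables round-trip to the generating weights", {
  for (seed in c(2, 17, 31)) {
    tr <- generate_truth(seed)
    lib <- generate_library(tr, sigma = 0)
    for (key in names(tr$models)) {
      f <- fit_enhancer(lib, key, tr$models[[key]]$K)
      expect_equal(f$configurations$weight,
                   tr$models[[key]]$configurations$weight,
                   tolerance = 1e-9)
    }
  }
})

test_that("recovered weights degrade gracefully with measurement noise", {
  med_err <- function(sigma) {
    errs <- purrr::map(1:60, function(s) {
      tr <- generate_truth(s)
      lib <- generate_library(tr, sigma = sigma, seed = s + 500)
      tryCatch(
        unlist(purrr::map(names(tr$models), function(k) {
          f <- fit_enhancer(lib, k, tr$models[[k]]$K)
          abs(f$configurations$weight -
                tr$models[[k]]$configurations$weight) /
            pmax(tr$models[[k]]$configurations$weight, 1e-12)
        })),
        error = function(e) NULL) # noisy table can be infeasible
    })
    stats::median(unlist(purrr::compact(errs)))
  }
  e0 <- med_err(0); e1 <- med_err(0.05); e2 <- med_err(0.2)
  expect_lt(e0, 1e-9)
  expect_lt(e0, e1)
  expect_lt(e1, e2)
})

test_that("implied single-site occupancy falls as K grows", {
  tb <- fixture_table()
  occ <- function(K) {
    m <- fit_enhancer(tb, "scl19", K)
    w <- m$configurations$weight[m$configurations$id == "G"]
    w / (K + w)
  }
  Ks <- c(900, 2000, 10000)
  os <- purrr::map_dbl(Ks, occ)
  expect_true(all(diff(os) < 0))
})

test_that("relaxed least-squares fit agrees with the exact fit on clean data", {
  tb <- fixture_table()
  me <- fit_enhancer(tb, "scl19", K = 900)
  mr <- fit_enhancer(tb, "scl19", K = 900, method = "relaxed")
  expect_equal(mr$configurations$weight, me$configurations$weight,
               tolerance = 1e-3)
})
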