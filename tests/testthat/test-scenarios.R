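test_that("default calibration satisfies its documented anchors", {
  p <- default_parameters()
  expect_identical(p$pelican$N0, 100)
  expect_identical(p$policy$hcr_share, 0.87)
  expect_equal(p$pelican$Gamma_a + p$pelican$Gamma_s +
                 p$pelican$Gamma_other, 1)
  expect_silent(validate_params(p))
  # derived mean recruitment balances natural + predation mortality at
  # the unfished design point
  P <- predation_mortality(p$pelican$Xa_o, p$pelican$Xs_o,
                           p$halibut$X0, p$halibut)
  expect_equal(p$anchovy$r_bar, p$anchovy$M + P[["Pa"]])
  expect_equal(p$sardine$r_bar, p$sardine$M + P[["Ps"]])
  # predation is a small share of forage mortality (weak top-down
  # control)
  expect_lt(P[["Pa"]] / (p$anchovy$M + P[["Pa"]]), 0.5)
  expect_lt(P[["Ps"]] / (p$sardine$M + P[["Ps"]]), 0.5)
  # sardine-dominant Pelican diet
  expect_gt(p$pelican$Gamma_s, p$pelican$Gamma_a)
})

test_that("parameter validation names the offending field", {
  p <- default_parameters()
  p$pelican$Gamma_a <- 0.9
  p$pelican$Gamma_s <- 0.9
  expect_error(validate_params(p), "Gamma")
  p <- default_parameters()
  p$econ$sardine$c2 <- 0
  expect_error(validate_params(p), "c2")
  p <- default_parameters()
  p$anchovy$w_r <- p$anchovy$w_inf + 1
  expect_error(validate_params(p), "w_r")
})

test_that("config files override defaults field-by-field", {
  empty <- tempfile(fileext = ".yaml")
  writeLines("", empty)
  expect_equal(load_config(empty), default_parameters())

  cfg <- tempfile(fileext = ".yaml")
  writeLines("econ:\n  delta: 0.10", cfg)
  p <- load_config(cfg)
  expect_equal(p$econ$delta, 0.10)
  p$econ$delta <- default_parameters()$econ$delta
  expect_equal(p, default_parameters())

  bad <- tempfile(fileext = ".yaml")
  writeLines(c("pelican:", "  Gamma_a: 0.9", "  Gamma_s: 0.9"), bad)
  expect_error(load_config(bad), "Gamma")

  unk <- tempfile(fileext = ".yaml")
  writeLines("sardine:\n  no_such_field: 1", unk)
  expect_error(load_config(unk), "unknown config key")

  expect_error(load_config(tempfile()), "not found")

  # the shipped example override loads and validates
  ex <- system.file("extdata", "example_calibration.yaml",
                    package = "forageweb")
  pex <- load_config(ex)
  expect_equal(pex$econ$delta, 0.07)
  expect_equal(pex$pelican$Gamma_a + pex$pelican$Gamma_s +
                 pex$pelican$Gamma_other, 1)
})

test_that("recruitment forcings realize the variability scenarios", {
  p <- default_parameters()
  fc <- make_recruitment_forcing("constant", p)
  expect_equal(fc$anchovy$A, 0)
  expect_equal(fc$sardine$A, 0)

  tgrid <- seq(0, p$anchovy$p, length.out = 401)
  r_of <- function(f, sp) {
    fp <- p[[sp]]
    fp[c("A", "p", "s")] <- f[[sp]][c("A", "p", "s")]
    recruitment_rate(tgrid, fp)
  }
  fs <- make_recruitment_forcing("synchronous", p)
  expect_equal(cor(r_of(fs, "anchovy"), r_of(fs, "sardine")), 1)

  fa <- make_recruitment_forcing("anti_synchronous", p)
  # phases offset by half a period: exactly opposite on the log scale
  expect_equal(cor(log(r_of(fa, "anchovy")), log(r_of(fa, "sardine"))), -1)
  expect_lt(cor(r_of(fa, "anchovy"), r_of(fa, "sardine")), -0.9)

  fl <- make_recruitment_forcing("anti_synchronous_long_sardine", p)
  expect_equal(fl$sardine$p, 2 * fl$anchovy$p)

  expect_error(make_recruitment_forcing("white_noise", p))
})

test_that("regime definitions partition the fished species", {
  labels <- c(optimization_regimes(), "OA_all", "Moratorium_all",
              "Moratorium:A+S")
  for (lb in labels) {
    reg <- regime_definition(lb)
    all_sp <- sort(c(reg$optimized, reg$open_access, reg$closed))
    expect_identical(all_sp, sort(c("anchovy", "sardine", "halibut")),
                     info = lb)
    expect_length(intersect(reg$optimized, reg$open_access), 0)
    expect_length(intersect(reg$optimized, reg$closed), 0)
  }
  expect_length(optimization_regimes(), 7)
  expect_identical(regime_definition("A+S")$optimized,
                   c("anchovy", "sardine"))
  expect_identical(regime_definition("Moratorium:S")$closed, "sardine")
  expect_error(regime_definition("Q"))
})

test_that("the sensitivity suite produces the six documented variants", {
  base <- fw_scenario(regime = "A+S", forcing = "synchronous")
  suite <- sensitivity_suite(base)
  expect_length(suite, 6)
  expect_setequal(names(suite),
                  c("higher_discount", "higher_forage_prices",
                    "decoupled_survival", "decoupled_recruitment",
                    "half_initial", "long_sardine"))
  expect_equal(suite$higher_discount$params$econ$delta, 0.10)
  expect_equal(suite$higher_forage_prices$params$econ$sardine$p_tilde,
               1.25 * base$params$econ$sardine$p_tilde)
  expect_identical(suite$decoupled_survival$params$pelican$theta_s[2], 0)
  expect_identical(suite$decoupled_recruitment$params$pelican$theta_r[2], 0)
  expect_equal(suite$half_initial$params$anchovy$X0,
               0.5 * base$params$anchovy$X0)
  expect_equal(suite$long_sardine$forcing$mode,
               "anti_synchronous_long_sardine")
  # every variant still passes the type invariants
  for (v in suite) expect_silent(validate_params(v$params))
})

test_that("scenario construction applies forcing and checks psi", {
  sc <- fw_scenario(regime = "A+S+H", forcing = "anti_synchronous")
  expect_equal(sc$params$sardine$s, sc$params$anchovy$s + 180)
  expect_equal(sc$name, "A+S+H/anti_synchronous")
  expect_error(fw_scenario(psi = 0.5), "psi")
  expect_silent(fw_scenario(psi = 0.2))
})
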