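test_that("degenerate sites reduce to the sedimentation term", {
  tr <- toy_traits()
  bare <- uniform_survey(c(sand = 1000))
  b <- site_budget(bare, tr)
  expect_equal(b$gross, 0)
  expect_equal(b$net, 0.4)
  expect_equal(b$net_with_acanthaster, 0.4)

  muddy <- uniform_survey(c(sand = 1000), regime = "high_terrigenous")
  expect_equal(site_budget(muddy, tr)$net, -0.4)
})

test_that("a hand-built site matches spreadsheet arithmetic end to end", {
  tr <- toy_traits()
  sv <- uniform_survey(
    c(coral_A = 200, coral_B = 100, coralline_algae = 50, macroborer = 10),
    planar = 800,
    urchins = data.frame(group = c("Diadema", "Echinometra"),
                         diameter_cm = c(8, 4.5)),
    fish = data.frame(species = c("parrot_X", "parrot_Y"),
                      length_cm = c(30, 18)),
    acanthaster_count = 6
  )
  b <- site_budget(sv, tr)

  r <- 1000 / 800
  gross_coral <- oracle_coral_calcification(r, c(20, 10), c(1.0, 0.8),
                                            c(1.2, 1.8), c(1.0, 2.0))
  ca <- r * oracle_ca(0.05)
  D <- (20 * 1.2 + 10 * 1.8) / 30
  pf <- oracle_parrotfish(c(30, 18), c(20, 12), D, 720)
  ue <- oracle_urchin(c("Diadema", "Echinometra"), c(8, 4.5), 36)
  mb <- oracle_macroboring(0.01)
  gross <- gross_coral + ca
  net <- gross + 0.4 - (pf + ue + mb)
  cots <- oracle_acanthaster(6, 6, D, 30, gross)

  expect_equal(b$gross, gross, tolerance = 1e-9)
  expect_equal(b$erosion$total, pf + ue + mb, tolerance = 1e-9)
  expect_equal(b$net, net, tolerance = 1e-9)
  expect_equal(b$acanthaster$reduction, cots$reduction, tolerance = 1e-9)
  expect_equal(b$net_with_acanthaster, net - cots$reduction,
               tolerance = 1e-9)
  expect_equal(b$accretion,
               vertical_accretion(net - cots$reduction), tolerance = 1e-9)
})

test_that("net with Acanthaster never exceeds net, equality without sea stars", {
  tr <- toy_traits()
  for (seed in 1:10) {
    sv <- random_survey(seed)
    b <- suppressWarnings(site_budget(sv, tr))
    expect_lte(b$net_with_acanthaster, b$net + 1e-12)
    if (sv$acanthaster_count == 0) {
      expect_equal(b$net_with_acanthaster, b$net)
    }
  }
})

fake_budget <- function(site_id, island, habitat, gross, parrotfish = 0,
                        urchin = 0, macro = 0, cots = 0, sed = 0.4) {
  structure(list(
    site_id = site_id, island = island, habitat = habitat,
    sediment_regime = "normal", gross = gross, gross_coral = gross, ca = 0,
    per_taxon = c(coral_A = gross),
    sedimentation = sed,
    erosion = total_erosion(parrotfish, urchin, macro),
    acanthaster = structure(list(reduction = cots, raw_reduction = cots,
                                 density_per_300m2 = 0,
                                 outbreak_flag = FALSE),
                            class = "acanthaster_impact"),
    net = gross + sed - (parrotfish + urchin + macro),
    net_with_acanthaster = gross + sed - (parrotfish + urchin + macro) - cots,
    accretion = 0,
    cover = list(live_coral_cover = 20, rugosity = 1.3, coral_density = 1.4)
  ), class = "carbonate_budget")
}

test_that("habitat summary reports group means and sample sd", {
  budgets <- list(
    fake_budget("a", "IslA", "inner", gross = 6),
    fake_budget("b", "IslA", "inner", gross = 10),
    fake_budget("c", "IslA", "outer", gross = 8)
  )
  s <- habitat_summary(budgets)
  inner <- s[s$group == "IslA inner", ]
  expect_equal(inner$gross_mean, 8)
  expect_equal(inner$gross_sd, sqrt(((6 - 8)^2 + (10 - 8)^2) / 1),
               tolerance = 1e-12)
  expect_equal(inner$n, 2)
  # single-site group: sd reported as 0, flagged by n = 1
  outer <- s[s$group == "IslA outer", ]
  expect_equal(outer$gross_sd, 0)
  expect_equal(outer$n, 1)
  # order invariance
  s2 <- habitat_summary(budgets[c(3, 1, 2)])
  expect_equal(s2[order(s2$group), ], s[order(s$group), ],
               ignore_attr = TRUE)
  # grazer erosion excludes macroboring and Acanthaster
  b2 <- list(fake_budget("a", "I", "inner", 5, parrotfish = 0.02,
                         urchin = 0.01, macro = 0.5, cots = 1),
             fake_budget("b", "I", "inner", 5))
  s3 <- habitat_summary(b2)
  expect_equal(s3$erosion_mean[s3$group == "I inner"], 0.015)
})

test_that("species contributions rank, normalise and accumulate", {
  budgets <- list(
    structure(list(per_taxon = c(A = 5, B = 3, C = 2), ca = 0),
              class = "carbonate_budget")
  )
  # single-taxon degenerate case
  one <- list(structure(list(per_taxon = c(A = 4), ca = 0),
                        class = "carbonate_budget"))
  expect_equal(species_contributions(one)$share_pct, 100)

  sc <- species_contributions(budgets)
  expect_equal(sc$taxon, c("A", "B", "C"))
  expect_equal(sc$share_pct, c(50, 30, 20))
  expect_equal(sc$cumulative_pct, c(50, 80, 100))
  expect_equal(sum(sc$share_pct), 100)
})

test_that("accretion conversion and sea-level comparison behave analytically", {
  expect_equal(vertical_accretion(0), 0)
  # concave quadratic with maximum at -1/(2 alpha)
  alpha <- -0.01949
  peak <- -1 / (2 * alpha)
  expect_equal(peak, 25.654, tolerance = 1e-3)
  cp <- seq(0, peak, length.out = 50)
  expect_true(all(diff(vertical_accretion(cp)) > 0))
  expect_lt(vertical_accretion(peak + 1), vertical_accretion(peak))
  expect_true(all(diff(vertical_accretion(cp), differences = 2) < 1e-9))

  expect_true(keeps_up(9, "RCP8.5"))   # boundary counts as keeping up
  expect_false(keeps_up(8.99, "RCP8.5"))
  expect_equal(sea_level_scenarios()$rise_mm_yr, c(5, 6.5, 6.7, 9))
  expect_error(keeps_up(5, "RCP1.9"), "unknown scenario")
})
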