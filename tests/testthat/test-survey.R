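test_that("per-taxon cover, rugosity and density follow their definitions", {
  tr <- toy_traits()
  # one taxon over 200 cm of every 1000 cm tape -> 20 %
  sv <- uniform_survey(c(coral_A = 200))
  cov <- site_cover(sv, tr)
  expect_equal(unname(cov$cover["coral_A"]), 20)
  expect_equal(cov$live_coral_cover, 20)

  # contour 1000 / planar 800 on all transects -> rugosity 1.25
  sv <- uniform_survey(c(coral_A = 200), planar = 800)
  expect_equal(site_cover(sv, tr)$rugosity, 1.25)

  # two corals at 10 % each, densities 1.2 and 1.8 -> D = 1.5
  sv <- uniform_survey(c(coral_A = 100, coral_B = 100))
  cov <- site_cover(sv, tr)
  expect_equal(cov$coral_density, 1.5)
  expect_equal(cov$live_coral_cover, 20)

  # coralline algae and macroborer come back as proportions
  sv <- uniform_survey(c(coral_A = 100, coralline_algae = 50,
                         macroborer = 10))
  cov <- site_cover(sv, tr)
  expect_equal(cov$pca, 0.05)
  expect_equal(cov$plamc, 0.01)
})

test_that("cover is invariant to segment order and length scaling", {
  tr <- toy_traits()
  base <- uniform_survey(c(coral_A = 150, coral_B = 250,
                           coralline_algae = 100))
  ref <- site_cover(base, tr)

  # permute segment rows within transects
  perm <- base
  set.seed(4)
  perm$benthic <- perm$benthic[sample(nrow(perm$benthic)), ]
  expect_equal(site_cover(perm, tr)$cover, ref$cover)

  # scale every length by a constant
  scaled <- uniform_survey(c(coral_A = 300, coral_B = 500,
                             coralline_algae = 200), contour = 2000,
                           planar = 2000)
  expect_equal(site_cover(scaled, tr)$cover, ref$cover)
})

test_that("cover bounds hold across random surveys", {
  tr <- toy_traits()
  for (seed in 1:25) {
    cov <- site_cover(random_survey(seed), tr)
    expect_gte(cov$live_coral_cover, 0)
    expect_lte(cov$live_coral_cover, 100)
    expect_lte(sum(cov$cover), 100 + 1e-9)
    expect_gte(cov$rugosity, 1)
  }
})

test_that("validation rejects malformed surveys", {
  # rugosity invariant: planar may not exceed contour
  expect_error(
    uniform_survey(c(coral_A = 100), contour = 1000, planar = 1100),
    "rugosity"
  )
  expect_error(
    uniform_survey(c(coral_A = 100), habitat = "lagoon"),
    "habitat"
  )
  expect_error(
    uniform_survey(c(coral_A = 100), regime = "muddy"),
    "sediment_regime"
  )
  # segments must sum to the contour length
  expect_error(
    site_survey("S", "I", "inner",
                benthic = data.frame(transect_no = 1, taxon = "coral_A",
                                     intercept_cm = 900),
                geometry = data.frame(transect_no = 1, contour_cm = 1000,
                                      planar_cm = 900)),
    "sum to the contour"
  )
  expect_error(
    uniform_survey(c(coral_A = 100),
                   urchins = data.frame(group = "Tripneustes",
                                        diameter_cm = 5)),
    "urchin group"
  )
  expect_error(uniform_survey(c(coral_A = 100), acanthaster_count = -1))
})

test_that("unmatched benthic taxa are reported by name", {
  sv <- uniform_survey(c(coral_A = 100, Mystery_coral = 50))
  expect_error(site_cover(sv, toy_traits()), "Mystery_coral")
})

test_that("write/read round-trips survey structures", {
  dir <- withr::local_tempdir()
  tr <- toy_traits()
  s1 <- random_survey(11, "A1")
  s2 <- random_survey(12, "A2")
  write_survey(list(A1 = s1, A2 = s2), dir)
  back <- read_survey(file.path(dir, "benthic.csv"),
                      file.path(dir, "mobile.csv"),
                      file.path(dir, "fish.csv"))
  expect_named(back, c("A1", "A2"))
  expect_equal(length(back), 2)
  for (nm in c("A1", "A2")) {
    orig <- get(ifelse(nm == "A1", "s1", "s2"))
    expect_equal(nrow(back[[nm]]$geometry), 6)
    expect_equal(site_cover(back[[nm]], tr), site_cover(orig, tr))
    expect_equal(back[[nm]]$acanthaster_count, orig$acanthaster_count)
    expect_equal(sort(back[[nm]]$urchins$diameter_cm),
                 sort(orig$urchins$diameter_cm))
    expect_equal(sort(back[[nm]]$fish$length_cm),
                 sort(orig$fish$length_cm))
  }
})

test_that("readers flag schema problems by column and row", {
  dir <- withr::local_tempdir()
  write_survey(list(A1 = random_survey(3, "A1")), dir)
  # drop a required column
  bn <- read.csv(file.path(dir, "benthic.csv"))
  write.csv(bn[, setdiff(names(bn), "planar_cm")],
            file.path(dir, "bad.csv"), row.names = FALSE)
  expect_error(
    read_survey(file.path(dir, "bad.csv"), file.path(dir, "mobile.csv"),
                file.path(dir, "fish.csv")),
    "planar_cm"
  )
  # negative intercept names the row
  bn2 <- bn
  bn2$intercept_cm[3] <- -5
  bn2$intercept_cm[1] <- bn2$intercept_cm[1] + bn$intercept_cm[3] + 5
  write.csv(bn2, file.path(dir, "bad2.csv"), row.names = FALSE)
  expect_error(
    read_survey(file.path(dir, "bad2.csv"), file.path(dir, "mobile.csv"),
                file.path(dir, "fish.csv")),
    "row\\(s\\) 3"
  )
  expect_error(
    read_survey(file.path(dir, "nope.csv"), file.path(dir, "mobile.csv"),
                file.path(dir, "fish.csv")),
    "not found"
  )
})
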