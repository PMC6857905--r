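test_that("parrotfish bite allometries match their closed forms", {
  expect_equal(bite_volume(30), exp(1.32 + 0.06 * 30) / 1000)
  expect_equal(bite_volume(10), exp(1.92) / 1000)
  # strictly increasing in length
  L <- seq(5, 60, by = 5)
  expect_true(all(diff(bite_volume(L)) > 0))
  expect_error(bite_volume(0), "length")

  # logistic midpoint at length 2.46 / 0.089
  expect_equal(scar_proportion(2.46 / 0.089), 0.5)
  expect_equal(scar_proportion(40), 1 / (1 + exp(-1.1)))
  expect_true(all(scar_proportion(L) > 0 & scar_proportion(L) < 1))

  expect_equal(bite_rate(30, brc = 20), 708)
  # clamped at zero for large fish / small brc
  expect_equal(bite_rate(100, brc = 1), 0)
  expect_true(all(diff(bite_rate(L, brc = 20)) <= 0))
  expect_error(bite_rate(10, brc = NA), "brc")
})

test_that("parrotfish erosion is additive and oracle-consistent", {
  tr <- toy_traits()
  expect_equal(parrotfish_erosion(data.frame(species = character(),
                                             length_cm = numeric()),
                                  1.5, tr, 720), 0)
  one <- data.frame(species = "parrot_X", length_cm = 30)
  two <- rbind(one, one)
  e1 <- parrotfish_erosion(one, 1.5, tr, 120)
  expect_equal(parrotfish_erosion(two, 1.5, tr, 120), 2 * e1)
  expect_equal(e1, oracle_parrotfish(30, 20, 1.5, 120), tolerance = 1e-12)
})

test_that("species without a brc entry fall back with a warning", {
  tr <- toy_traits()
  fsh <- data.frame(species = "Scarus_unknownus", length_cm = 25)
  expect_warning(e <- parrotfish_erosion(fsh, 1.4, tr, 720, default_brc = 20),
                 "Scarus_unknownus")
  expect_equal(e, oracle_parrotfish(25, 20, 1.4, 720), tolerance = 1e-12)
})

test_that("urchin group allometries match their printed forms", {
  expect_equal(urchin_erosion(data.frame(group = "Diadema",
                                         diameter_cm = 10), 1),
               0.000001 * 10^3.42 * 0.365 * 0.57)
  expect_equal(urchin_erosion(data.frame(group = "Echinometra",
                                         diameter_cm = 5), 1),
               0.0004 * 5^1.98 * 0.365 * 0.57)
  expect_equal(urchin_erosion(data.frame(group = "Other",
                                         diameter_cm = 7), 1),
               0.0001 * 7^2.32 * 0.365 * 0.57)
  expect_equal(urchin_erosion(data.frame(group = character(),
                                         diameter_cm = numeric()), 36), 0)
  expect_error(urchin_erosion(data.frame(group = "Toxopneustes",
                                         diameter_cm = 5), 36),
               "unknown urchin group")
})

test_that("macroboring erosion is linear with full-cover limit mec", {
  expect_equal(macroboring_erosion(0), 0)
  expect_equal(macroboring_erosion(0.01), 0.1)
  expect_equal(macroboring_erosion(1, mec = 10), 10)
  expect_error(macroboring_erosion(1.5), "proportion")
})

test_that("total erosion sums components and rejects negatives", {
  e <- total_erosion(0.03, 0.01, 0.1)
  expect_equal(e$total, 0.14)
  expect_equal(total_erosion(0, 0, 0)$total, 0)
  expect_equal(total_erosion(0.1, 0.03, 0.01)$total, e$total)
  expect_error(total_erosion(-0.1, 0, 0), "non-negative")
})

test_that("erosion is order-invariant and matches the row oracle on random records", {
  tr <- toy_traits()
  for (seed in 1:15) {
    set.seed(seed)
    n <- 20
    fsh <- data.frame(species = sample(c("parrot_X", "parrot_Y"), n, TRUE),
                      length_cm = round(runif(n, 8, 50)))
    urch <- data.frame(group = sample(c("Diadema", "Echinometra", "Other"),
                                      n, TRUE),
                       diameter_cm = round(runif(n, 1, 14) * 2) / 2)
    D <- runif(1, 1, 1.8)
    brcs <- tr$brc[match(fsh$species, tr$taxon)]

    pf <- parrotfish_erosion(fsh, D, tr, 720)
    expect_equal(pf, oracle_parrotfish(fsh$length_cm, brcs, D, 720),
                 tolerance = 1e-9)
    ue <- urchin_erosion(urch, 36)
    expect_equal(ue, oracle_urchin(urch$group, urch$diameter_cm, 36),
                 tolerance = 1e-9)

    idx <- sample(n)
    expect_equal(parrotfish_erosion(fsh[idx, ], D, tr, 720), pf)
    expect_equal(urchin_erosion(urch[idx, ], 36), ue)
    expect_gte(pf, 0)
    expect_gte(ue, 0)
  }
})
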