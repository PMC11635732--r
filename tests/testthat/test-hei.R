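test_that("two days pool by summation; missing or zero-energy days are excluded", {
  r1 <- intake_row(2400, list(dairy = 2))
  r1$energy_d1 <- 1000; r1$energy_d2 <- 1400
  pooled <- pool_days(r1)
  expect_equal(pooled$energy, 2400)
  expect_equal(pooled$dairy, 2)
  expect_true(pooled$scorable)

  r2 <- intake_row(2000, list())
  r2$energy_d2 <- NA
  p2 <- pool_days(r2)
  expect_false(p2$scorable)
  expect_equal(p2$unscorable_reason, "incomplete_recall")

  r3 <- intake_row(0, list())
  p3 <- pool_days(r3)
  expect_false(p3$scorable)
  expect_equal(p3$unscorable_reason, "zero_energy")
  expect_true(all(is.na(score_hei(p3)$hei_total)))
})

test_that("component scoring clips at the standards and is linear between them", {
  std <- hei_standards()
  tf <- std[std$component == "total_fruits", ]  # full points at 0.8 cup/1000
  expect_equal(score_component(1.6, 2000, tf), 5)    # exactly at the standard
  expect_equal(score_component(5.0, 2000, tf), 5)    # beyond: clipped
  expect_equal(score_component(0.8, 2000, tf), 2.5)  # halfway density 0.4
  expect_equal(score_component(0, 2000, tf), 0)
  sod <- std[std$component == "sodium", ]            # moderation, 1.1 to 2.0
  expect_equal(score_component(2 * 1.1, 2000, sod), 10)
  expect_equal(score_component(2 * 2.0, 2000, sod), 0)
  expect_equal(score_component(2 * 1.55, 2000, sod), 5)
  bad <- tf; bad$zero_standard <- bad$full_standard
  expect_error(score_component(1, 2000, bad), "malformed")
})

test_that("an ideal menu meeting every maximum standard scores exactly 100", {
  e <- 2000
  ideal <- list(total_fruits = 0.8 * 2, whole_fruits = 0.4 * 2,
                total_vegetables = 1.1 * 2, greens_beans = 0.2 * 2,
                whole_grains = 1.5 * 2, dairy = 1.3 * 2,
                total_protein = 2.5 * 2, seafood_plant_protein = 0.8 * 2,
                refined_grains = 1.8 * 2, sodium = 1.1 * 2,
                added_sugars = 0.065 * e / 16,     # 6.5% of energy
                sat_fat = 0.08 * e / 9,            # 8% of energy
                mufa_pufa = 2.5 * 0.08 * e / 9)    # ratio 2.5
  hei <- score_hei(pool_days(intake_row(e, ideal)))
  expect_equal(hei$hei_total, 100)
})

test_that("all-zero intake scores the standards-implied floor/ceiling pattern", {
  hei <- score_hei(pool_days(intake_row(2000, list())))
  std <- hei_standards()
  for (comp in std$component[std$direction == "adequacy"]) {
    expect_equal(hei[[paste0("score_", comp)]], 0, info = comp)
  }
  for (comp in std$component[std$direction == "moderation"]) {
    expect_equal(hei[[paste0("score_", comp)]],
                 std$max_points[std$component == comp], info = comp)
  }
  expect_equal(hei$hei_total, 40)  # the four moderation maxima
})

test_that("a hand-scored toy menu matches component by component", {
  e <- 2000
  menu <- list(total_fruits = 0.8, whole_fruits = 0.3, total_vegetables = 1.1,
               greens_beans = 0.1, whole_grains = 1.2, dairy = 1.0,
               total_protein = 2.0, seafood_plant_protein = 0.4,
               refined_grains = 5.0, sodium = 3.0, added_sugars = 15,
               sat_fat = 20, mufa_pufa = 30)
  hei <- score_hei(pool_days(intake_row(e, menu)))
  # densities are per 1000 kcal of the 2000-kcal pool; scores by hand:
  hand <- c(
    total_fruits = 5 * 0.4 / 0.8,             # 2.5
    whole_fruits = 5 * 0.15 / 0.4,            # 1.875
    total_vegetables = 5 * 0.55 / 1.1,        # 2.5
    greens_beans = 5 * 0.05 / 0.2,            # 1.25
    whole_grains = 10 * 0.6 / 1.5,            # 4
    dairy = 10 * 0.5 / 1.3,                   # 3.8462
    total_protein = 5 * 1.0 / 2.5,            # 2
    seafood_plant_protein = 5 * 0.2 / 0.8,    # 1.25
    fatty_acids = 10 * (30 / 20 - 1.2) / 1.3, # ratio 1.5 -> 2.3077
    refined_grains = 10 * (4.3 - 2.5) / 2.5,  # 7.2
    sodium = 10 * (2.0 - 1.5) / 0.9,          # 5.5556
    added_sugars = 10 * (26 - 12) / 19.5,     # 15 tsp = 12% energy
    sat_fat = 10 * (16 - 9) / 8)              # 20 g = 9% energy
  for (comp in names(hand)) {
    expect_equal(hei[[paste0("score_", comp)]], unname(hand[comp]),
                 tolerance = 1e-12, info = comp)
  }
  expect_equal(hei$hei_total, sum(hand), tolerance = 1e-12)
})

test_that("density scores are invariant to doubling amounts and energy", {
  set.seed(71)
  menu <- list(total_fruits = 1, whole_fruits = 0.5, total_vegetables = 1.5,
               greens_beans = 0.2, whole_grains = 2, dairy = 1.5,
               total_protein = 3, seafood_plant_protein = 0.7,
               refined_grains = 4, sodium = 2.5, added_sugars = 10,
               sat_fat = 15, mufa_pufa = 25)
  h1 <- score_hei(pool_days(intake_row(1800, menu)))
  h2 <- score_hei(pool_days(intake_row(3600, lapply(menu, `*`, 2))))
  expect_equal(h1$hei_total, h2$hei_total, tolerance = 1e-12)
})

test_that("components are monotone in their stated direction under perturbation", {
  std <- hei_standards()
  e <- 2000
  base <- list(total_fruits = 0.6, whole_fruits = 0.3, total_vegetables = 1.2,
               greens_beans = 0.15, whole_grains = 1.5, dairy = 1.2,
               total_protein = 2.5, seafood_plant_protein = 0.6,
               refined_grains = 4, sodium = 2.6, added_sugars = 12,
               sat_fat = 18, mufa_pufa = 30)
  h0 <- score_hei(pool_days(intake_row(e, base)))
  for (comp in setdiff(std$component, "fatty_acids")) {
    up <- base
    up[[comp]] <- base[[comp]] * 1.3
    h1 <- score_hei(pool_days(intake_row(e, up)))
    dirn <- std$direction[std$component == comp]
    d <- h1[[paste0("score_", comp)]] - h0[[paste0("score_", comp)]]
    if (dirn == "adequacy") expect_gte(d, 0) else expect_lte(d, 0)
  }
})

test_that("the bundled standards are well formed", {
  std <- hei_standards()
  expect_equal(nrow(std), 13)
  expect_equal(sum(std$max_points), 100)
  expect_setequal(std$direction, c("adequacy", "moderation"))
})
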