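test_that("z-sum index matches the hand-computed two-unit case", {
  m <- rbind(a = c(0, 0, 0), b = c(2, 2, 2))
  colnames(m) <- c("c1", "c2", "c3")
  expect_equal(unname(zsum_index(m)), c(-3, 3))
  expect_error(zsum_index(rbind(c(1, 2), c(1, 5))), "component_1")
  m2 <- rbind(c(1, 1), c(1, 2))
  colnames(m2) <- c("flat", "ok")
  expect_error(zsum_index(m2), "flat")
})

test_that("z-sum index is invariant to unit order and affine component rescaling", {
  set.seed(3)
  m <- matrix(rnorm(30), 10, 3)
  idx <- zsum_index(m)
  perm <- sample(10)
  expect_equal(zsum_index(m[perm, ]), idx[perm])
  m2 <- m
  m2[, 2] <- 100 + 7 * m[, 2]
  expect_equal(zsum_index(m2), idx)
  expect_equal(mean(idx), 0)
})

test_that("AFO exposure follows the inverse-squared-distance form", {
  one <- data.frame(x = 0, y = 0, animal_units = 100)
  expect_equal(afo_exposure(1000, 0, one), 100)
  two <- data.frame(x = c(0, 0), y = c(0, 0), animal_units = c(100, 400))
  two$x <- c(0, 0); two$y <- c(0, 0)
  afos <- data.frame(x = c(1000, 2000), y = c(0, 0),
                     animal_units = c(100, 400))
  expect_equal(afo_exposure(0, 0, afos), 100 + 100)
  expect_equal(afo_exposure(0, 0, afos[0, ]), 0)
  # the distance floor caps the contribution of co-located operations
  close <- data.frame(x = 10, y = 0, animal_units = 50)
  expect_equal(afo_exposure(0, 0, close), 50 / 0.1^2)
})

test_that("AFO exposure is monotone in distance and animal units", {
  set.seed(5)
  afos <- data.frame(x = runif(6, 0, 5000), y = runif(6, 0, 5000),
                     animal_units = runif(6, 50, 500))
  base <- afo_exposure(2500, 2500, afos)
  further <- afos
  further$x <- 2500 + (afos$x - 2500) * 1.5
  further$y <- 2500 + (afos$y - 2500) * 1.5
  expect_lte(afo_exposure(2500, 2500, further), base)
  bigger <- afos; bigger$animal_units <- afos$animal_units * 2
  expect_gte(afo_exposure(2500, 2500, bigger), base)
})

test_that("well counts respect the radius and drill-date boundaries", {
  birth <- as.Date("2008-06-01")
  wells <- data.frame(x = c(19900, 20100, 5000), y = 0,
                      drill_date = c(birth - 1, birth - 1, birth + 1))
  expect_equal(wells_within(0, 0, wells[1, ], birth), 1L)
  expect_equal(wells_within(0, 0, wells[2, ], birth), 0L)
  expect_equal(wells_within(0, 0, wells[3, ], birth), 0L)
  set.seed(2)
  w <- data.frame(x = runif(25, 0, 40000), y = runif(25, 0, 40000),
                  drill_date = birth + sample(-300:300, 25, TRUE))
  got <- wells_within(12000, 9000, w, birth)
  manual <- sum(sqrt((w$x - 12000)^2 + (w$y - 9000)^2) / 1000 <= 20 &
                  w$drill_date <= birth)
  expect_equal(got, manual)
})

test_that("road distance matches geometry and a densified brute force", {
  road <- data.frame(x1 = -1000, y1 = 0, x2 = 1000, y2 = 0, major = TRUE)
  expect_equal(road_distance(0, 100, road), 100)
  expect_equal(road_distance(500, 0, road), 0)
  expect_error(road_distance(0, 0, road[0, ]), "no road")
  set.seed(8)
  roads <- data.frame(x1 = runif(5, 0, 5000), y1 = runif(5, 0, 5000),
                      x2 = runif(5, 0, 5000), y2 = runif(5, 0, 5000),
                      major = TRUE)
  px <- 2100; py <- 3300
  dens <- min(vapply(seq_len(5), function(k) {
    t <- seq(0, 1, length.out = 4001)
    min(sqrt((roads$x1[k] + t * (roads$x2[k] - roads$x1[k]) - px)^2 +
               (roads$y1[k] + t * (roads$y2[k] - roads$y1[k]) - py)^2))
  }, numeric(1)))
  expect_equal(road_distance(px, py, roads), dens, tolerance = 1e-5)
})

test_that("Medical Assistance needs more than two qualifying encounters", {
  expect_equal(as.character(medical_assistance(c(0, 2, 3, 10))),
               c("never", "never", "ever", "ever"))
})

test_that("smoking status keys on records inside the gestation interval", {
  conc <- as.Date("2007-01-01"); birth <- as.Date("2007-10-01")
  expect_equal(as.character(smoking_status(conc - 1, conc, birth)), "never")
  expect_equal(as.character(smoking_status(conc + 120, conc, birth)), "ever")
  expect_equal(as.character(smoking_status(as.Date(NA), conc, birth)), "never")
})

test_that("the covariate panel derives classes and quartiles correctly", {
  cfg <- tiny_config(seed = 10)
  raster <- simulate_raster(cfg)
  sim <- simulate_cohort(cfg, raster)
  layers <- simulate_point_layers(cfg)
  panel <- build_covariate_panel(sim$cohort, sim$communities, layers)
  expect_equal(nrow(panel), nrow(sim$cohort))
  # BMI boundaries exactly at 18.5 / 25 / 30
  b <- cut(c(18.4, 18.5, 24.9, 25, 29.9, 30), c(-Inf, 18.5, 25, 30, Inf),
           right = FALSE, labels = c("under", "normal", "over", "obese"))
  expect_equal(as.character(b),
               c("under", "normal", "normal", "over", "over", "obese"))
  expect_equal(panel$maternal_age2, panel$maternal_age^2)
  # CSD quartiles partition the births into near-equal groups (community-level
  # ties allowed)
  sizes <- table(panel$csd_quartile)
  expect_equal(length(sizes), 4L)
  expect_identical(sum(sizes), nrow(panel))
  # smoking/assistance flags agree with the record-level rules
  expect_identical(panel$medical_assistance,
                   medical_assistance(sim$cohort$ma_qualifying_encounters))
})
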