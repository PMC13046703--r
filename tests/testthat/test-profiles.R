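test_that("component registry matches the published component inventory", {
  reg <- component_registry()
  expect_equal(nrow(reg), 70)
  expect_false(anyDuplicated(reg$component) > 0)
  counts <- table(reg$category)
  expect_equal(unname(counts[["Routine chemical components"]]), 5)
  expect_equal(unname(counts[["Cations and anions"]]), 6)
  expect_equal(unname(counts[["Polyphenols"]]), 5)
  expect_equal(unname(counts[["Polyacids and higher fatty acids"]]), 12)
  expect_equal(unname(counts[["Amino acids"]]), 21)
  expect_equal(unname(counts[["Amadori compounds"]]), 17)
  expect_equal(unname(counts[["Others"]]), 4)
})

test_that("country profiles carry the published means and sds", {
  prof <- load_country_profiles()
  expect_named(prof, c("China", "United States", "Brazil", "Zimbabwe",
                       "Zambia"))
  expect_equal(vapply(prof, function(p) p$n, 0),
               c(China = 1269, `United States` = 64, Brazil = 129,
                 Zimbabwe = 154, Zambia = 101))
  for (p in prof) {
    expect_length(p$mean, 70)
    expect_length(p$sd, 70)
    expect_true(all(p$sd >= 0))
  }
  expect_equal(prof$China$mean[["Total alkaloids"]], 2.50)
  expect_equal(prof$China$sd[["Total alkaloids"]], 0.60)
  expect_equal(prof$Zambia$mean[["Succinic acid"]], 0.41)
  expect_equal(prof$Zambia$sd[["Succinic acid"]], 0.04)
  expect_equal(prof$China$mean[["Fru-Pro"]], 9223.37)
  expect_equal(prof$China$sd[["Fru-Pro"]], 2485.89)
})

test_that("region counts map provinces to China and sum to 1717", {
  rc <- load_region_counts()
  expect_equal(nrow(rc), 13)
  expect_equal(sum(rc$n), 1717)
  expect_equal(rc$n[rc$region == "Yunnan"], 360)
  expect_equal(rc$n[rc$region == "Shandong"], 24)
  provinces <- c("Yunnan", "Sichuan", "Guizhou", "Chongqing", "Henan",
                 "Hunan", "Fujian", "Shandong", "Heilongjiang")
  expect_true(all(rc$country[rc$region %in% provinces] == "China"))
  expect_false(anyDuplicated(rc$region) > 0)
})

test_that("generated tables have the configured shape and labels", {
  tbl <- generate_chem_table(n_noise_features = 2, seed = 3)
  expect_s3_class(tbl, "chem_table")
  expect_equal(nrow(tbl), 1717)
  expect_length(chem_components(tbl), 72)
  expect_equal(as.vector(table(tbl$region)[load_region_counts()$region]),
               load_region_counts()$n)
  comp <- component_registry()$component
  expect_true(all(sapply(tbl[comp], function(x) all(x >= 0))))
  expect_true(all(tbl$pH > 0 & tbl$pH < 14))
})

test_that("zero-sd profiles reproduce the configured means exactly", {
  means <- list(P = c(a = 1, b = 5), Q = c(a = 2, b = 0.5))
  sds <- list(P = c(a = 0, b = 0), Q = c(a = 0, b = 0))
  counts <- data.frame(region = c("P", "Q"), country = c("P", "Q"),
                       n = c(4, 3))
  tbl <- generate_chem_table(toy_profiles(means, sds), counts,
                             region_offsets = NULL, seed = 1)
  expect_equal(unique(tbl$a[tbl$region == "P"]), 1)
  expect_equal(unique(tbl$b[tbl$region == "Q"]), 0.5)
})

test_that("generation is bit-identical under the same seed", {
  t1 <- generate_chem_table(n_noise_features = 1, seed = 11)
  t2 <- generate_chem_table(n_noise_features = 1, seed = 11)
  t3 <- generate_chem_table(n_noise_features = 1, seed = 12)
  expect_identical(t1, t2)
  expect_false(identical(t1, t3))
})

test_that("invalid generator inputs are rejected", {
  prof <- load_country_profiles()
  counts <- load_region_counts()
  bad_off <- matrix(0, 13, 69, dimnames = list(counts$region, NULL))
  expect_error(generate_chem_table(region_offsets = bad_off),
               "one column per component")
  prof$China$sd[1] <- -1
  expect_error(generate_chem_table(profiles = prof), "negative standard")
  expect_error(generate_chem_table(separation_scale = -1), ">= 0")
})

test_that("class sample means recover configured means across seeds", {
  # 4 sd / sqrt(n) band, checked per country for three representative
  # components over 20 seeds
  prof <- load_country_profiles()
  comps <- c("Total alkaloids", "Fru-Pro", "Succinic acid")
  ok <- 0; total <- 0
  noise_ok <- 0; noise_total <- 0
  for (seed in 1:20) {
    tbl <- generate_chem_table(region_offsets = NULL, n_noise_features = 1,
                               seed = seed)
    for (ct in names(prof)) {
      sub <- tbl[tbl$country == ct, ]
      for (cm in comps) {
        mu <- prof[[ct]]$mean[[cm]]; sd <- prof[[ct]]$sd[[cm]]
        total <- total + 1
        if (abs(mean(sub[[cm]]) - mu) < 4 * sd / sqrt(nrow(sub))) {
          ok <- ok + 1
        }
      }
    }
    for (ct in names(prof)) {
      noise_total <- noise_total + 1
      r <- abs(cor(tbl$noise_01, as.numeric(tbl$country == ct)))
      if (r < 0.15) noise_ok <- noise_ok + 1
    }
  }
  expect_gte(ok / total, 0.99)
  expect_gte(noise_ok / noise_total, 0.95)
})

test_that("zero truncation cannot inflate comfortable means much", {
  # for components with mean >= 2 sd, truncating negatives moves the
  # realized mean by far less than 0.5 sd
  prof <- load_country_profiles()
  tbl <- generate_chem_table(region_offsets = NULL, seed = 5)
  for (ct in c("China", "Brazil")) {
    sub <- tbl[tbl$country == ct, ]
    p <- prof[[ct]]
    comfortable <- names(p$mean)[p$mean >= 2 * p$sd & p$sd > 0]
    for (cm in comfortable) {
      expect_lt(mean(sub[[cm]]) - p$mean[[cm]], 0.5 * p$sd[[cm]])
    }
  }
})

test_that("chem tables round-trip through CSV", {
  tbl <- blob_table(5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_chem_table(tbl, path)
  back <- read_chem_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tbl))
})

test_that("malformed chem table files are rejected with coordinates", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("country,f1", "X,1"), path)
  expect_error(read_chem_table(path), "region")
  writeLines(c("region,country,f1", "A,X,1", "A,X,oops"), path)
  expect_error(read_chem_table(path), "row 2")
})
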