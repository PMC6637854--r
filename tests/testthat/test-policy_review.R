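test_that("keyword filter applies the inclusion rule case-insensitively", {
  recs <- data.frame(
    id = c("a", "b", "c", "d"),
    jurisdiction = "C01",
    domain = "food environment",
    category = "school fruit and vegetable provision schemes",
    description = c(
      "school scheme providing a minimum quantity of fruit daily",
      "promote healthy eating",
      "Vegetable subsidy",
      "supports fruits and vegetables in canteens"),
    stringsAsFactors = FALSE)
  kept <- filter_fv_policies(recs)
  expect_identical(kept$id, c("a", "c", "d"))
  # general healthy-eating records are excluded
  expect_false("b" %in% kept$id)
  # adding keywords never shrinks the matched set
  more <- filter_fv_policies(recs, keywords = c("fruit", "vegetable", "eating"))
  expect_true(all(kept$id %in% more$id))
  expect_identical(more$id, c("a", "b", "c", "d"))
  # empty input passes through
  expect_identical(nrow(filter_fv_policies(recs[0, ])), 0L)
})

test_that("bloc records expand to the full membership", {
  recs <- data.frame(
    id = c("eu1", "cc1", "pi1", "n1"),
    jurisdiction = c("EU", "Caribbean Community",
                     "Pacific Island Nations and Territories", "C05"),
    domain = "food environment",
    category = "subsidies to reduce the price of fruits and vegetables",
    description = "subsidy on fruit",
    stringsAsFactors = FALSE)
  out <- expand_regions(recs)
  expect_identical(sum(out$id == "eu1"), 28L)
  expect_identical(sum(out$id == "cc1"), 15L)
  expect_identical(sum(out$id == "pi1"), 22L)
  # country-level record passes through unchanged
  native <- out[out$id == "n1", ]
  expect_identical(nrow(native), 1L)
  expect_identical(native$country, "C05")
  expect_true(is.na(native$source_bloc))
  # expansion conservation: total = sum of memberships + native records
  expect_identical(nrow(out), 28L + 15L + 22L + 1L)
  # provenance retained
  expect_true(all(out$source_bloc[out$id == "eu1"] == "EU"))
  # unknown jurisdiction with a closed country list is an error
  expect_error(expand_regions(recs, countries = "C01"), "membership error")
})

test_that("category-to-rung mapping is total and matches the anchors", {
  tax <- nourishing_taxonomy()
  expect_identical(anyDuplicated(tax$category), 0L)
  expect_true(all(tax$rung %in% nuffield_rungs()))
  # store-owner incentives act on consumer access, not consumer incentives
  expect_identical(
    map_to_nuffield("incentives for store-owners to locate in underserved areas"),
    "enable choice")
  expect_identical(map_to_nuffield("food-based dietary guidelines"),
                   "provide information")
  expect_identical(
    map_to_nuffield("subsidies to reduce the price of fruits and vegetables"),
    "guide choice with incentives")
  expect_error(map_to_nuffield("mystery category"), "taxonomy error")
  expect_identical(length(nuffield_rungs()), 7L)
})

test_that("tabulation counts distinct countries and keeps empty rungs", {
  region_map <- data.frame(country = c("C01", "C02", "C03"),
                           region = c("Europe", "Europe", "Latin America"),
                           stringsAsFactors = FALSE)
  recs <- data.frame(
    id = c("p1", "p2", "p3", "p4"),
    jurisdiction = c("C01", "C01", "C02", "C03"),
    domain = c("behaviour change communication",
               "behaviour change communication",
               "food environment", "food system/supply"),
    category = c("food-based dietary guidelines",
                 "public awareness and mass-media campaigns",
                 "subsidies to reduce the price of fruits and vegetables",
                 "school fruit and vegetable provision schemes"),
    description = "fruit",
    country = c("C01", "C01", "C02", "C03"),
    source_bloc = NA_character_,
    stringsAsFactors = FALSE)
  tab <- tabulate_policies(recs, region_map)
  grid <- tab$by_region_rung
  # full region x rung index, zeros included
  expect_identical(nrow(grid), 2L * 7L)
  # two provide-information records for C01 count as one country
  expect_identical(
    grid$n[grid$region == "Europe" & grid$rung == "provide information"], 1L)
  expect_identical(
    grid$n[grid$region == "Europe" &
           grid$rung == "guide choice with incentives"], 1L)
  # unobserved rungs report zero rows rather than disappearing
  expect_identical(
    grid$n[grid$rung == "eliminate choice"], c(0L, 0L))
  observed <- unique(grid$rung[grid$n > 0])
  expect_identical(length(setdiff(nuffield_rungs(), observed)), 4L)
  # counting policies instead of countries restores the duplicate
  tabp <- tabulate_policies(recs, region_map, count = "policies")
  expect_identical(
    tabp$by_region_rung$n[tabp$by_region_rung$region == "Europe" &
                          tabp$by_region_rung$rung == "provide information"],
    2L)
  # domain totals count records
  expect_identical(sum(tab$by_domain$n), 4L)
  # empty input: all-zero table with the full rung index
  empty <- tabulate_policies(recs[0, ], region_map)
  expect_true(all(empty$by_region_rung$n == 0))
  expect_identical(nrow(empty$by_region_rung), 14L)
  # a country missing from the region map is a grouping error
  expect_error(tabulate_policies(recs, region_map[1:2, ]), "grouping error")
})

test_that("country counts never exceed the region's country total", {
  set.seed(31)
  db <- generate_policy_db(300, seed = 31, fv_fraction = 0.5)
  fv <- filter_fv_policies(db)
  membership <- default_region_membership()
  expanded <- expand_regions(fv, membership)
  region_map <- rbind(
    data.frame(country = sprintf("C%02d", 1:20), region = "native",
               stringsAsFactors = FALSE),
    do.call(rbind, lapply(names(membership), function(b) {
      data.frame(country = membership[[b]], region = b,
                 stringsAsFactors = FALSE)
    })))
  tab <- tabulate_policies(expanded, region_map)$by_region_rung
  sizes <- table(region_map$region)
  expect_true(all(tab$n <= as.integer(sizes[tab$region])))
})
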