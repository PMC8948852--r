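test_that("sheet template has 33 items, 30 manual and 3 automated synergy items", {
  tmpl <- fma_sheet_template()
  expect_equal(nrow(tmpl), 33)
  expect_equal(sum(tmpl$mode == "manual"), 30)
  auto <- tmpl[tmpl$mode == "automated", ]
  expect_equal(nrow(auto), 3)
  expect_true(all(auto$section == "A-II"))
  expect_setequal(auto$movement, c("shoulder_abduction", "elbow_flexion",
                                   "elbow_extension"))
  expect_false(anyDuplicated(tmpl$item_id) > 0)
})

test_that("automated item scoring maps AROM to the 0/1/2 ordinal", {
  expect_equal(score_a2_item(170, "shoulder_abduction"), 2L)
  expect_equal(score_a2_item(100, "shoulder_abduction"), 1L)
  expect_equal(score_a2_item(10, "shoulder_abduction"), 0L)
  expect_equal(score_a2_item(150, "shoulder_abduction"), 2L)  # at threshold
  expect_equal(score_a2_item(89.99, "shoulder_abduction"), 0L)
  expect_error(score_a2_item(90, "wrist_circumduction"), "no thresholds")
  expect_error(score_a2_item(90, "shoulder_abduction",
                             list(shoulder_abduction = list(full = 80,
                                                            partial = 90))),
               "partial < full")

  # accepts an arom_result directly
  st <- clean_stream(10, abduction = 170)
  ar <- extract_arom(angle_series(st, "shoulder_abduction", "right"))
  expect_equal(score_a2_item(ar), 2L)
})

test_that("sheet assembly enforces completeness and uniqueness", {
  sheet <- assemble_sheet(manual_items_all(2L),
                          list(shoulder_abduction = 2, elbow_flexion = 2,
                               elbow_extension = 2))
  expect_s3_class(sheet, "fma_sheet")
  expect_equal(total_score(sheet), 66)

  m29 <- manual_items_all(2L)[-1, ]
  expect_error(assemble_sheet(m29, list(shoulder_abduction = 2,
                                        elbow_flexion = 2,
                                        elbow_extension = 2)),
               "missing manual item.*A1-1")
  dup <- rbind(manual_items_all(2L), data.frame(item_id = "A1-1", score = 2L))
  expect_error(assemble_sheet(dup, list()), "duplicated item_id")
  expect_error(assemble_sheet(manual_items_all(2L),
                              list(shoulder_abduction = 2, elbow_flexion = 2)),
               "elbow_extension")
})

test_that("total score arithmetic and bounds", {
  zero <- assemble_sheet(manual_items_all(0L),
                         list(shoulder_abduction = 0, elbow_flexion = 0,
                              elbow_extension = 0))
  expect_equal(total_score(zero), 0)
  mixed <- assemble_sheet(manual_items_all(2L),
                          list(shoulder_abduction = 1, elbow_flexion = 1,
                               elbow_extension = 1))
  expect_equal(total_score(mixed), 63)

  # monotone non-decreasing in every item score
  set.seed(21)
  for (k in 1:10) {
    m <- manual_items_all()
    m$score <- sample(0:2, 30, replace = TRUE)
    auto <- as.list(stats::setNames(sample(0:2, 3, replace = TRUE),
                                    c("shoulder_abduction", "elbow_flexion",
                                      "elbow_extension")))
    t0 <- total_score(assemble_sheet(m, auto))
    expect_gte(t0, 0); expect_lte(t0, 66)
    bump <- which(m$score < 2)
    if (length(bump)) {
      m$score[bump[1]] <- m$score[bump[1]] + 1L
      expect_equal(total_score(assemble_sheet(m, auto)), t0 + 1)
    }
  }
})

test_that("hybrid bands partition 0-66: total, disjoint, exhaustive", {
  bands <- capacity_bands("hybrid")
  cats <- vapply(0:66, classify_capacity, character(1), bands = bands)
  expect_false(any(cats == "unclassified"))
  # each score falls in exactly one band
  for (tt in 0:66)
    expect_equal(sum(bands$lower <= tt & tt <= bands$upper), 1)
  expect_equal(cats[40 + 1], "limited")
  expect_equal(cats[50 + 1], "notable")
  expect_equal(cats[66 + 1], "total")
  expect_equal(cats[22 + 1], "none")
  expect_equal(cats[23 + 1], "low")
  expect_equal(cats[52 + 1], "total")
  expect_error(classify_capacity(67), "0..66")
})

test_that("interface scheme leaves 48-52 unclassified; discussion resolves shared endpoints upward", {
  intf <- capacity_bands("interface")
  expect_equal(classify_capacity(50, intf), "unclassified")
  expect_equal(classify_capacity(31, intf), "low")
  expect_equal(classify_capacity(53, intf), "total")
  disc <- capacity_bands("discussion")
  expect_equal(classify_capacity(47, disc), "notable")
  expect_equal(classify_capacity(52, disc), "total")
})

test_that("bundled study-group totals classify to the 78% total-capacity share", {
  co <- fixture_cohort()
  scores <- co$study$fma_total
  cats <- vapply(scores, classify_capacity, character(1))
  expect_equal(sum(cats == "total"), 14)
  sh <- cohort_classification_shares(scores)
  expect_equal(sh$percent[sh$category == "total"], 78)
  expect_equal(sh$count[sh$category == "limited"], 3)
  expect_equal(sh$percent[sh$category == "limited"], 17)
  expect_equal(sh$count[sh$category == "notable"], 1)
  expect_equal(sh$percent[sh$category == "notable"], 6)
})
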