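test_that("packaged detection table loads with the published structure", {
  tbl <- fixture_table()
  expect_equal(nrow(tbl), 10)
  expect_named(tbl, c("species", "common_name", "size_class",
                      protocol_levels()))
  delicata <- tbl[tbl$species == "Lampropholis delicata", ]
  expect_equal(
    unlist(delicata[protocol_levels()]),
    c("All-74" = 10, "CT-74" = 10, "All-16" = 10, "CT-16" = 10,
      "LI" = 10, "AR" = 10, "PF" = 7)
  )
  # column sums drive everything downstream
  expect_equal(
    vapply(protocol_levels(), function(p) sum(tbl[[p]]), numeric(1)),
    c("All-74" = 60, "CT-74" = 53, "All-16" = 43, "CT-16" = 34,
      "LI" = 30, "AR" = 23, "PF" = 16)
  )
})

test_that("detection-table validation names the species and constraint", {
  tbl <- fixture_table()
  bad <- tbl
  bad[1, "AR"] <- 3L; bad[1, "PF"] <- 0L; bad[1, "LI"] <- 2L
  bad[1, c("All-16", "All-74")] <- 10L
  # |AR ∪ PF| >= max(AR, PF) forces LI >= 3
  expect_error(validate_detection_table(bad),
               "Lampropholis delicata.*max\\(AR, PF\\) <= LI")
  bad2 <- tbl
  bad2[2, "CT-16"] <- 5L
  expect_error(validate_detection_table(bad2),
               "Saproscincus mustelinus.*CT-16 <= CT-74")
  bad3 <- tbl
  bad3[3, "All-74"] <- 11L
  expect_error(validate_detection_table(bad3), "count range")
  # joint camera/LI overlap infeasibility not caught by single inequalities:
  # CT-16 ∩ LI would exceed CT-74 ∩ LI
  bad4 <- tbl
  bad4[2, protocol_levels()] <-
    as.list(c("All-74" = 4, "CT-74" = 2, "All-16" = 2, "CT-16" = 2,
              "LI" = 2, "AR" = 1, "PF" = 1))
  expect_error(validate_detection_table(bad4), "overlap feasibility")
})

test_that("detection tables round-trip through CSV", {
  tbl <- fixture_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_detection_table(tbl, path)
  expect_equal(load_detection_table(path), tbl)
})

test_that("packaged cost profiles reproduce the published expenses", {
  prof <- fixture_profiles()
  expect_equal(nrow(prof), 7)
  ct74 <- prof[prof$protocol == "CT-74", ]
  expect_equal(ct74$equipment, 26582)
  expect_equal(ct74$vehicle, 400)
  expect_equal(ct74$consumables, 500)
  expect_equal(ct74$labour_h, 41)
  # camera protocols have no refuge/pitfall deployment line: blank reads as 0
  expect_equal(ct74$deploy_labour_h, 0)
  expect_equal(ct74$deploy_vehicle, 0)
  li <- prof[prof$protocol == "LI", ]
  expect_equal(li$deploy_labour_h, 55)
  expect_equal(li$deploy_vehicle, 300)
  expect_equal(li$equipment, 2280)
})

test_that("cost profile loader rejects malformed tables", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("item,All-74,CT-74,All-16,CT-16,LI,AR,PF",
               "equipment,1,1,1,1,1,1,1"), path)
  expect_error(load_cost_profiles(path), "missing row")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("item,All-74,CT-74,All-16,CT-16,LI,AR,PF",
               "equipment,1,1,1,1,1,1,-5",
               "vehicle,0,0,0,0,0,0,0",
               "consumables,0,0,0,0,0,0,0",
               "labour_h,0,0,0,0,0,0,0",
               "deploy_labour_h,0,0,0,0,0,0,0",
               "deploy_vehicle,0,0,0,0,0,0,0"), path2)
  expect_error(load_cost_profiles(path2), "negative")
})

test_that("survey effort reproduces the field-effort bookkeeping", {
  eff <- survey_effort(survey_design())
  val <- function(q) eff$value[eff$quantity == q]
  expect_equal(val("pitfall_trap_days"), 640)
  expect_equal(val("ar_trap_days"), 320)
  expect_equal(val("li_trap_days"), 960)
  expect_equal(val("inspections"), 1920)
  expect_equal(val("camera_trap_days"), 4 * 10 * 69)
  # outages are an explicit adjustment, not a modelled schedule
  eff2 <- survey_effort(survey_design(), camera_outage_days = 100)
  expect_equal(eff2$value[eff2$quantity == "camera_trap_days"], 2660)
  # degenerate design: no survey days, no effort
  eff0 <- survey_effort(survey_design(li_days = 0, ct_days = 0))
  expect_true(all(eff0$value == 0))
})
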