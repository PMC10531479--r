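# Structural-alert library and screening

test_that("the default library ships the 14 named aquatic-toxicity alerts", {
  lib <- load_alert_library()
  expect_length(lib$alerts, 14L)
  expect_setequal(names(lib$alerts),
                  c("TA662", "TA665", "TA642", "TA628", "TA11521", "TA667",
                    "TA617", "TA626", "TA631", "TA1181", "TA1176", "TA659",
                    "TA638", "TA634"))
})

test_that("every alert fires on its positive control and not on its paired negative", {
  lib <- load_alert_library()
  ctl <- alert_controls()
  expect_equal(nrow(ctl), 28L)
  hits <- screen(ctl$smiles, lib, ids = paste0("ctl", seq_len(nrow(ctl))))
  for (k in seq_len(nrow(ctl))) {
    id <- paste0("ctl", k)
    fired <- ctl$alert_id[k] %in% hits$alert_id[hits$id == id]
    if (ctl$role[k] == "positive") {
      expect_true(fired, label = sprintf("%s fires on %s (%s)",
                                         ctl$alert_id[k], ctl$smiles[k],
                                         ctl$name[k]))
    } else {
      expect_false(fired, label = sprintf("%s silent on %s (%s)",
                                          ctl$alert_id[k], ctl$smiles[k],
                                          ctl$name[k]))
    }
  }
})

test_that("screening matches hand-derived alert assignments", {
  lib <- load_alert_library()
  hits <- screen(c("CCCN", "CCO", "c1ccccc1"), lib, ids = c("a", "b", "c"))
  a <- hits$alert_id[hits$id == "a"]
  expect_true("TA665" %in% a)        # primary alkyl amine
  expect_false("TA662" %in% a)       # not secondary/tertiary
  expect_equal(hits$alert_id[hits$id == "b"], "TA659")
  expect_equal(sum(hits$id == "c"), 0L)  # benzene is alert-free
  # four ammonium groups -> match count 4
  tetra <- assemble_smiles("cage", rep("C[NH3+]", 4), seed = 2)
  h4 <- screen(tetra, lib, ids = "t")
  expect_equal(h4$count[h4$alert_id == "TA642"], 4L)
})

test_that("screening is invariant to how the input SMILES is written", {
  lib <- load_alert_library()
  h1 <- screen("OCC", lib, ids = "m")
  h2 <- screen("CCO", lib, ids = "m")
  expect_equal(h1[order(h1$alert_id), c("alert_id", "count")],
               h2[order(h2$alert_id), c("alert_id", "count")],
               ignore_attr = TRUE)
})

test_that("the library round-trips through serialization", {
  lib <- load_alert_library()
  path <- tempfile(fileext = ".json")
  write_alert_library(lib, path)
  back <- load_alert_library(path, include_defaults = FALSE)
  expect_equal(names(back$alerts), names(lib$alerts))
  expect_equal(lapply(back$alerts, function(a) unlist(a$smarts)),
               lapply(lib$alerts, function(a) unlist(a$smarts)))
})

test_that("user files extend or override and malformed files are rejected", {
  user <- tempfile(fileext = ".json")
  writeLines('[{"alert_id":"TA9999","name":"test alert","smarts":["[OX2H]"]}]',
             user)
  lib <- load_alert_library(user)
  expect_length(lib$alerts, 15L)
  # duplicate alert_id within a user file is an error
  writeLines(paste0('[{"alert_id":"TA1","name":"a","smarts":["C"]},',
                    '{"alert_id":"TA1","name":"b","smarts":["N"]}]'), user)
  expect_fd_error(load_alert_library(user), "load")
  # invalid SMARTS is named
  writeLines('[{"alert_id":"TA2","name":"bad","smarts":["[[Q"]}]', user)
  err <- tryCatch(load_alert_library(user), error = identity)
  expect_s3_class(err, "fdtox_load")
  expect_match(conditionMessage(err), "TA2")
})

test_that("defaults disabled with no user file gives an empty library and no hits", {
  lib <- load_alert_library(include_defaults = FALSE)
  expect_length(lib$alerts, 0L)
  hits <- screen(c("CCO", "CCCN"), lib)
  expect_equal(nrow(hits), 0L)
})

test_that("screening report conserves rows, groups by alert sets, and flags review cases", {
  ids <- c("A", "B", "C", "D")
  scores <- c(7300, 6500, 4200, 5600)
  hits <- data.frame(id = c("B", "B", "D"),
                     alert_id = c("TA642", "TA665", "TA642"),
                     name = "x", count = c(4L, 1L, 2L))
  rep <- screening_report(ids, scores, hits, threshold = 5000)
  expect_equal(nrow(rep), 4L)
  expect_equal(rep$id, ids)
  expect_true(rep$review[1])                 # high score, no alerts
  expect_false(rep$review[2])                # high score but alerted
  expect_false(rep$review[3])                # low score
  expect_equal(rep$group_key[2], "TA642+TA665")
  expect_equal(rep$group_key[3], "none")
  expect_fd_error(
    screening_report(c("A", "A"), c(1, 2),
                     data.frame(id = character(0), alert_id = character(0),
                                name = character(0), count = integer(0))),
    "join")
  expect_fd_error(
    screening_report("A", 1, data.frame(id = "Z", alert_id = "TA1",
                                        name = "x", count = 1L)),
    "join")
})
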