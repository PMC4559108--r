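test_that("the classifier matches its decision table on every pattern", {
  patterns <- expand.grid(rt = c(TRUE, FALSE), c4 = c(TRUE, FALSE),
                          pres = c(TRUE, FALSE), sgn = c("+", "-"),
                          stringsAsFactors = FALSE)
  expected_class <- function(rt, c4, pres) {
    if (!rt) return("stable_or_indeterminate")
    if (c4 || pres) return("chemical")
    "bacterial"
  }
  for (i in seq_len(nrow(patterns))) {
    pt <- patterns[i, ]
    recs <- rbind(make_record("m1", "RT", pt$rt, pt$sgn),
                  make_record("m1", "C4", pt$c4, pt$sgn),
                  make_record("m1", "Pres", pt$pres, pt$sgn))
    call <- classify(recs)
    expect_identical(call$class, expected_class(pt$rt, pt$c4, pt$pres),
                     label = paste("pattern", i))
    if (call$class != "stable_or_indeterminate") {
      expect_identical(call$sign, pt$sgn)
      expect_identical(call$reason, "")
    }
  }
})

test_that("conflicting trend signs are flagged, never silently classified", {
  recs <- rbind(make_record("m1", "RT", TRUE, "+"),
                make_record("m1", "C4", TRUE, "-"))
  call <- classify(recs)
  expect_identical(call$class, "stable_or_indeterminate")
  expect_match(call$reason, "conflicting")
  # opposite RT signs across experiments
  recs2 <- rbind(make_record("m2", "RT", TRUE, "+", experiment = "Exp1"),
                 make_record("m2", "RT", TRUE, "-", experiment = "Exp2"))
  expect_identical(classify(recs2)$class, "stable_or_indeterminate")
})

test_that("robust selection requires replicated RT significance and concordant C4 status", {
  both_rt_sig <- rbind(
    make_record("a", "RT", TRUE, "+", "Exp1"),
    make_record("a", "C4", FALSE, experiment = "Exp1"),
    make_record("a", "RT", TRUE, "+", "Exp2"),
    make_record("a", "C4", FALSE, experiment = "Exp2"))
  expect_identical(select_robust(both_rt_sig)$ids, "a")

  rt_discordant <- rbind(
    make_record("b", "RT", TRUE, "+", "Exp1"),
    make_record("b", "RT", FALSE, experiment = "Exp2"))
  expect_length(select_robust(rt_discordant)$ids, 0)

  c4_discordant <- rbind(
    make_record("c", "RT", TRUE, "+", "Exp1"),
    make_record("c", "C4", TRUE, "+", "Exp1"),
    make_record("c", "RT", TRUE, "+", "Exp2"),
    make_record("c", "C4", FALSE, experiment = "Exp2"))
  expect_length(select_robust(c4_discordant)$ids, 0)

  # measured in a single experiment: evaluated on that experiment alone
  single <- rbind(make_record("d", "RT", TRUE, "-", "Exp1"),
                  make_record("d", "C4", FALSE, experiment = "Exp1"))
  expect_identical(select_robust(single)$ids, "d")

  # Pres discordance does not block selection
  pres_discordant <- rbind(
    make_record("e", "RT", TRUE, "+", "Exp1"),
    make_record("e", "RT", TRUE, "+", "Exp2"),
    make_record("e", "Pres", TRUE, "+", "Exp2"))
  expect_identical(select_robust(pres_discordant)$ids, "e")
})

test_that("allow-listed metabolites are force-included, never auto-included", {
  recs <- rbind(make_record("x", "RT", FALSE),
                make_record("x", "C4", TRUE, "+"),
                make_record("y", "RT", TRUE, "+"))
  no_allow <- classify_calls(recs)
  expect_identical(no_allow$feature_id, "y")
  with_allow <- classify_calls(recs, allow_list = "x")
  expect_setequal(with_allow$feature_id, c("x", "y"))
  expect_identical(with_allow$class[with_allow$feature_id == "x"],
                   "stable_or_indeterminate")
  expect_warning(classify_calls(recs, allow_list = "ghost"), "absent")
})

test_that("summaries count classes and per-experiment metabolite sets", {
  empty <- summarize_calls(classify_calls(make_record("z", "RT", FALSE)[0, ]))
  expect_equal(sum(empty$class_counts$n), 0)

  calls <- rbind(classify(rbind(make_record("a", "RT", TRUE, "+"),
                                make_record("a", "C4", FALSE))),
                 classify(rbind(make_record("b", "RT", TRUE, "+"),
                                make_record("b", "C4", TRUE, "+"))))
  recs <- rbind(make_record("a", "RT", TRUE, "+", "Exp1"),
                make_record("b", "RT", TRUE, "+", "Exp1"),
                make_record("c", "RT", FALSE, experiment = "Exp1"),
                make_record("b", "RT", TRUE, "+", "Exp2"),
                make_record("c", "RT", FALSE, experiment = "Exp2"),
                make_record("d", "RT", FALSE, experiment = "Exp2"))
  s <- summarize_calls(calls, recs)
  cc <- s$class_counts
  expect_equal(cc$n[cc$class == "bacterial"], 1)
  expect_equal(cc$n[cc$class == "chemical"], 1)
  ec <- s$experiment_counts
  expect_equal(ec$n[ec$experiment == "Exp1"], 3)
  expect_equal(ec$n[ec$experiment == "Exp2"], 3)
  expect_equal(ec$n[ec$experiment == "common"], 2) # {b, c}
})

test_that("onset times attach to calls per condition", {
  recs <- rbind(make_record("a", "RT", TRUE, "+"),
                make_record("a", "C4", TRUE, "+"))
  ons <- data.frame(feature_id = c("a", "a"), experiment = "Exp1",
                    condition = c("RT", "C4"), onset_h = c(12, 48),
                    direction = "above", stringsAsFactors = FALSE)
  call <- classify(recs, onsets = ons)
  expect_equal(call$onset_rt_h, 12)
  expect_equal(call$onset_c4_h, 48)
  expect_true(is.na(call$onset_pres_h))
})
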