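test_that("group rectangles span member specimen means", {
  ref <- load_reference()
  groups <- group_records(ref)

  prob <- group_rectangle(groups$proboscideans, "proboscideans")
  expect_equal(prob$onar_interval, c(175852.0, 263151.7))

  yabe <- group_rectangle(ref[ref$taxon == "Yabe's giant deer", ])
  expect_equal(yabe$onar_interval, c(40086.5, 40086.5)) # point rectangle
  expect_equal(yabe$har_interval, c(350.0, 350.0))

  # members used exclude plexiform-only rows
  expect_false("SMY02Ra" %in% attr(yabe, "members"))

  pf_only <- ref[ref$specimen_id == "SMY02Ra", ]
  expect_error(group_rectangle(pf_only), "no member")

  # every member's own (mean, mean) point lies inside its group rectangle
  rects <- build_group_rectangles(ref, "group")
  lab <- load_taxon_groups()
  for (i in seq_len(nrow(ref))) {
    if (is.na(ref$mean_onar[i]) || is.na(ref$mean_har[i])) next
    g <- lab$group_label[lab$taxon == ref$taxon[i]]
    r <- rects[[g]]
    expect_true(ref$mean_onar[i] >= r$onar_interval[1] &&
                  ref$mean_onar[i] <= r$onar_interval[2])
    expect_true(ref$mean_har[i] >= r$har_interval[1] &&
                  ref$mean_har[i] <= r$har_interval[2])
  }
})

test_that("fragment rectangles run from lower-bound to upper-bound means", {
  intervals <- fragment_intervals()
  names(intervals) <- vapply(intervals, `[[`, "", "specimen_id")

  fk3 <- fragment_rectangle(intervals[["FK-B-003"]])
  expect_equal(round_report(fk3$onar_interval), c(18174.1, 24232.1))
  expect_equal(round_report(fk3$har_interval), c(478.7, 638.3))

  # FK-B-006's published upper mean (21248.2) was derived from unrounded
  # measurements; recomputing from the 1-dp table gives 21248.13
  fk6 <- fragment_rectangle(intervals[["FK-B-006"]])
  expect_equal(round_report(fk6$onar_interval[1]), 15936.1)
  expect_lt(abs(fk6$onar_interval[2] - 21248.2), 0.15)
  expect_equal(round_report(fk6$har_interval), c(500.5, 667.3))

  # identity shrinkage -> point rectangle
  ident <- apply_shrinkage_bounds(
    specimen_summary("Z", 5, 10000, 1000, 300, 50),
    shrinkage_model(upper_factor = 1))
  pr <- fragment_rectangle(ident)
  expect_equal(pr$onar_interval[1], pr$onar_interval[2])
})

test_that("rectangle overlap is closed, symmetric and reflexive", {
  a <- range_rectangle(c(0, 2), c(0, 2), "a")
  b <- range_rectangle(c(2, 4), c(1, 3), "b") # shares an edge: overlap
  c_ <- range_rectangle(c(5, 6), c(0, 2), "c")
  expect_true(rectangles_overlap(a, b))
  expect_true(rectangles_overlap(b, a))
  expect_true(rectangles_overlap(a, a))
  expect_false(rectangles_overlap(a, c_))
  # disjoint on one axis only is not overlap
  d <- range_rectangle(c(0, 2), c(5, 6), "d")
  expect_false(rectangles_overlap(a, d))
})

test_that("fragments overlap medium artiodactyls but not distant groups", {
  ref <- load_reference()
  rects <- build_group_rectangles(ref, "group")
  tax_rects <- build_group_rectangles(ref, "taxon")
  frs <- lapply(fragment_intervals(), fragment_rectangle)

  for (fr in frs) {
    expect_true(rectangles_overlap(fr, rects$medium_artiodactyls))
    expect_false(rectangles_overlap(fr, rects$human))
    expect_false(rectangles_overlap(fr, rects$proboscideans))
    expect_false(rectangles_overlap(fr, tax_rects[["Yabe's giant deer"]]))
  }

  # the marginal bison contact registers as overlap for FK-B-003 only
  overlap_large <- vapply(frs, rectangles_overlap,
                          logical(1), b = rects$large_artiodactyls)
  labels <- vapply(frs, `[[`, "", "label")
  expect_equal(unname(overlap_large[labels == "FK-B-003"]), TRUE)
  expect_equal(unname(overlap_large[labels == "FK-B-002"]), FALSE)
})

test_that("classification combines overlap and statistical exclusion", {
  ref <- load_reference()
  refs_stat <- filter_statistical_set(ref)
  intervals <- fragment_intervals()
  tables <- list(
    no_shrinkage = build_comparison_table(intervals, refs_stat, "no_shrinkage"),
    shrinkage_700 = build_comparison_table(intervals, refs_stat, "shrinkage_700"))
  rects <- build_group_rectangles(ref, "group")
  frs <- lapply(intervals, fragment_rectangle)
  names(frs) <- vapply(frs, `[[`, "", "label")

  rep3 <- classify_fragment(frs[["FK-B-003"]], rects, tables)
  expect_true("medium_artiodactyls" %in% rep3$candidates)
  expect_true("proboscideans" %in% names(rep3$excluded))
  expect_true("human" %in% names(rep3$excluded))
  expect_equal(length(intersect(rep3$candidates, names(rep3$excluded))), 0)

  # single-specimen taxon rectangle: no overlap + significant both
  # scenarios -> excluded
  tax_rects <- build_group_rectangles(ref, "taxon")
  rep_yabe <- classify_fragment(frs[["FK-B-003"]],
                                tax_rects["Yabe's giant deer"], tables)
  expect_true("Yabe's giant deer" %in% names(rep_yabe$excluded))

  # a rectangle equal to the fragment's own is always a candidate
  self_rect <- frs[["FK-B-003"]]
  attr(self_rect, "members") <- character(0)
  rep_self <- classify_fragment(frs[["FK-B-003"]], list(self = self_rect),
                                tables)
  expect_equal(rep_self$candidates, "self")

  expect_error(classify_fragment(frs[[1]], rects,
                                 tables["no_shrinkage"]),
               "missing scenario")
})

test_that("widening the shrinkage interval never shrinks the candidate set", {
  ref <- load_reference()
  rects <- build_group_rectangles(ref, "group")
  refs_stat <- filter_statistical_set(ref)
  prev <- NULL
  for (uf in c(0.9, 0.75, 0.6)) {
    intervals <- fragment_intervals(upper_factor = uf)
    tables <- list(
      no_shrinkage = build_comparison_table(intervals, refs_stat, "no_shrinkage"),
      shrinkage_700 = build_comparison_table(intervals, refs_stat, "shrinkage_700"))
    fr <- fragment_rectangle(intervals[[1]])
    cand <- classify_fragment(fr, rects, tables)$candidates
    if (!is.null(prev)) expect_true(all(prev %in% cand))
    prev <- cand
  }
})
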