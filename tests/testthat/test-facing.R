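TB <- time_bins(c(10, 30, 60))

per <- function(tag, st, et, z, role = "nurse") {
  out <- data.frame(tagID = rep_len(tag, length(st)), st = st, et = et,
                    zID = rep_len(z, length(st)),
                    tagRole = rep_len(role, length(st)),
                    stringsAsFactors = FALSE)
  attr(out, "role_scope") <-
    if (length(role) == 0 || role[1] == "nurse") "nurses_only" else "patients_only"
  out
}

test_that("overlap is the clipped intersection of half-open intervals", {
  expect_equal(period_overlap(100, 140, 120, 200), 20)
  expect_equal(period_overlap(0, 10, 10, 20), 0)  # touching
  expect_equal(period_overlap(0, 3600, 500, 560), 60)
  # symmetry and the length bound, over random pairs
  set.seed(3)
  a1 <- sample(0:50, 200, TRUE) * 4; a2 <- a1 + sample(1:20, 200, TRUE) * 4
  b1 <- sample(0:50, 200, TRUE) * 4; b2 <- b1 + sample(1:20, 200, TRUE) * 4
  expect_equal(period_overlap(a1, a2, b1, b2), period_overlap(b1, b2, a1, a2))
  expect_true(all(period_overlap(a1, a2, b1, b2) <= pmin(a2 - a1, b2 - b1)))
})

test_that("bins are left-open right-closed with an unbounded last bin", {
  expect_equal(overlap_bin(20, TB), 2L)
  expect_equal(overlap_bin(10, TB), 1L)  # boundary falls in the lower bin
  expect_equal(overlap_bin(3600, TB), 4L)
  expect_true(is.na(overlap_bin(0, TB)))
  expect_equal(overlap_bin(c(4, 11, 30, 31, 60, 61), TB), c(1L, 2L, 2L, 3L, 3L, 4L))
})

test_that("a single qualifying pair lands in the right cell", {
  np <- per("n1", 100, 140, 3)
  pp <- per("p1", 120, 200, 3, "patient:A")
  ft <- build_facing_table(np, pp, TB, "n1", c("A", "B"))
  expect_equal(sum(ft$counts), 1)
  expect_equal(ft$counts["n1", "A_10-30"], 1L)  # overlap 20 s -> second bin
  oracle <- slot_oracle_facing(np, pp, TB, "n1", c("A", "B"))
  expect_equal(unname(ft$counts), unname(oracle))
})

test_that("zone mismatch and empty inputs give all-zero tables", {
  np <- per("n1", 100, 140, 3)
  pp5 <- per("p1", 120, 200, 5, "patient:A")
  ft <- build_facing_table(np, pp5, TB, "n1", "A")
  expect_true(all(ft$counts == 0))
  ft2 <- build_facing_table(np, per("p", integer(0), integer(0), integer(0),
                                    character(0)), TB, c("n1", "n2"), c("A", "B"))
  expect_equal(dim(ft2$counts), c(2L, 8L))
  expect_true(all(ft2$counts == 0))
})

test_that("table counts match the per-slot co-location oracle on random instances", {
  set.seed(11)
  for (i in 1:25) {
    inst <- random_instance(sample(3:5, 1), sample(2:3, 1))
    ft <- build_facing_table(inst$nurse_periods, inst$patient_periods, TB,
                             inst$nurse_ids, inst$type_labels)
    oracle <- slot_oracle_facing(inst$nurse_periods, inst$patient_periods, TB,
                                 inst$nurse_ids, inst$type_labels)
    expect_equal(unname(ft$counts), unname(oracle))
  }
})

test_that("permuting period rows leaves the table unchanged", {
  set.seed(12)
  inst <- random_instance(4, 2)
  ft <- build_facing_table(inst$nurse_periods, inst$patient_periods, TB,
                           inst$nurse_ids, inst$type_labels)
  perm_n <- inst$nurse_periods[sample(nrow(inst$nurse_periods)), ]
  perm_p <- inst$patient_periods[sample(nrow(inst$patient_periods)), ]
  attr(perm_n, "role_scope") <- "nurses_only"
  attr(perm_p, "role_scope") <- "patients_only"
  ft2 <- build_facing_table(perm_n, perm_p, TB, inst$nurse_ids, inst$type_labels)
  expect_identical(ft$counts, ft2$counts)
})

test_that("unknown nurse tags and patient types are rejected", {
  np <- per("ghost", 0, 8, 1)
  pp <- per("p1", 0, 8, 1, "patient:Z")
  expect_error(build_facing_table(np, pp, TB, "n1", "A"), "unknown nurse")
  expect_error(build_facing_table(per("n1", 0, 8, 1), pp, TB, "n1", "A"),
               "unknown patient type")
  expect_error(build_facing_table(per("n1", 0, 8, 1),
                                  per("p1", 0, 8, 1, "oops"), TB, "n1", "A"),
               "patient:")
})

test_that("column layout is type-major with readable labels", {
  ft <- build_facing_table(per("n1", 0, 8, 1),
                           per("p1", 0, 8, 1, "patient:A"), TB, "n1", c("A", "B"))
  expect_equal(colnames(ft$counts)[1:4], c("A_0-10", "A_10-30", "A_30-60", "A_>60"))
  expect_equal(colnames(ft$counts)[5:8], c("B_0-10", "B_10-30", "B_30-60", "B_>60"))
})
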