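test_that("mode enumeration covers the power set with canonical labels", {
  d <- egfr_design()
  modes <- enumerate_modes(d)
  expect_equal(nrow(modes), 8L)
  reg <- lapply(modes$regulators, sort)
  names(reg) <- modes$label
  expect_equal(reg$A, character(0))
  expect_equal(reg$B, "other_receptors")
  expect_equal(reg$C, "isoforms_II_IV")
  expect_equal(reg$D, "isoform_I")
  expect_equal(reg$E, sort(c("isoforms_II_IV", "other_receptors")))
  expect_equal(reg$F, sort(c("isoform_I", "isoforms_II_IV",
                             "other_receptors")))
  expect_equal(reg$G, sort(c("isoform_I", "other_receptors")))
  expect_equal(reg$H, sort(c("isoform_I", "isoforms_II_IV")))

  d1 <- knockdown_design("r1", list(control = character(0)))
  expect_equal(nrow(enumerate_modes(d1)), 2L)
  d4 <- knockdown_design(paste0("r", 1:4), list(control = character(0)))
  expect_equal(nrow(enumerate_modes(d4)), 16L)
})

test_that("invalid designs are rejected", {
  expect_error(knockdown_design(character(0),
                                list(control = character(0))),
               "at least one regulator channel")
  expect_error(knockdown_design(c("r1", "r1"),
                                list(control = character(0))), "unique")
  expect_error(knockdown_design("r1", list(kd = "r1")), "control")
  expect_error(knockdown_design("r1", list(control = character(0),
                                           kd = "r9")), "unknown channels")
})

test_that("mode responses follow the surviving-channel rule", {
  d <- egfr_design()
  expect_equal(mode_response("H", "siRNA_ALL", d), 0L)
  expect_equal(mode_response("C", "siRNA_I", d), 1L)
  expect_equal(mode_response("A", "control", d), 0L)
  expect_equal(mode_response(character(0), "siRNA_ALL", d), 0L)
  expect_equal(mode_response(c("isoform_I", "isoforms_II_IV"),
                             "siRNA_I", d), 1L)
  # the siRNA_ALL column of the response table: only other-receptor routes
  modes <- enumerate_modes(d)
  resp_all <- vapply(modes$regulators, mode_response, integer(1),
                     treatment = "siRNA_ALL", design = d)
  expect_equal(modes$label[resp_all == 0L], c("A", "C", "D", "H"))
  expect_error(mode_response("Z", "control", d), "unknown mode")
})

test_that("the EGFR design reduces to the four published pattern groups", {
  pg <- egfr_patterns()
  expect_equal(pg$labels, c("a", "b", "c", "d"))
  expect_equal(pg$members$a, "A")
  expect_equal(sort(pg$members$b), c("B", "E", "F", "G"))
  expect_equal(sort(pg$members$c), c("C", "H"))
  expect_equal(pg$members$d, "D")
  expect_equal(unname(pg$indicators["a", ]), rep(0L, 6))
  expect_equal(unname(pg$indicators["b", ]), c(0L, 1L, 0L, 1L, 0L, 1L))
  expect_equal(unname(pg$indicators["c", ]), c(0L, 1L, 0L, 1L, 0L, 0L))
  expect_equal(unname(pg$indicators["d", ]), c(0L, 1L, 0L, 0L, 0L, 0L))
  expect_equal(unname(pg$confounded), c(FALSE, TRUE, TRUE, FALSE))
})

test_that("small designs reduce as enumerated by hand", {
  d1 <- knockdown_design("r1", list(control = character(0)))
  pg1 <- derive_pattern_groups(d1)
  expect_equal(length(pg1$labels), 2L)
  expect_equal(unname(pg1$indicators[1, ]), c(0L, 0L))
  expect_equal(unname(pg1$indicators[2, ]), c(0L, 1L))

  d2 <- knockdown_design(paste0("r", 1:3),
                         list(control = character(0),
                              kd_all = paste0("r", 1:3)))
  pg2 <- derive_pattern_groups(d2)
  expect_equal(length(pg2$labels), 2L)
  zero <- rowSums(pg2$indicators) == 0
  expect_equal(lengths(pg2$members)[zero], c(a = 1L))
  expect_equal(unname(lengths(pg2$members)[!zero]), 7L)
  expect_equal(unname(pg2$indicators[!zero, ]), c(0L, 1L, 0L, 0L))
})

test_that("pattern-group partition matches a brute-force oracle", {
  set.seed(42)
  for (rep in 1:40) {
    d <- random_design(sample(1:5, 1), sample(1:4, 1))
    expect_equal(package_partition(d), unname(oracle_partition(d)))
  }
})

test_that("mode bookkeeping invariants hold on random designs", {
  set.seed(7)
  for (rep in 1:25) {
    k <- sample(1:5, 1)
    d <- random_design(k, sample(1:4, 1))
    pg <- derive_pattern_groups(d)
    expect_equal(sum(lengths(pg$members)), 2^k)
    zero <- which(rowSums(pg$indicators) == 0)
    expect_length(zero, 1L)
    expect_equal(lengths(pg$members)[[zero]], 1L)
    expect_equal(enumerate_modes(d)$regulators[
      match(pg$members[[zero]], enumerate_modes(d)$label)][[1]],
      character(0))
  }
})

test_that("adding a treatment refines, never merges, the partition", {
  set.seed(99)
  for (rep in 1:15) {
    k <- sample(2:5, 1)
    d <- random_design(k, 4)
    for (t in 2:3) {
      d_small <- knockdown_design(d$channels, d$treatments[seq_len(t)])
      d_big <- knockdown_design(d$channels, d$treatments[seq_len(t + 1)])
      part_small <- package_partition(d_small)
      part_big <- package_partition(d_big)
      expect_gte(length(part_big), length(part_small))
      # every refined class is contained in exactly one coarse class
      for (cls in part_big) {
        members <- strsplit(cls, ";")[[1]]
        holder <- vapply(part_small, function(cs)
          all(members %in% strsplit(cs, ";")[[1]]), logical(1))
        expect_equal(sum(holder), 1L)
      }
    }
  }
})

test_that("YAML design files round-trip through read_design", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "stimulus: EGF",
    "channels: [isoform_I, isoforms_II_IV, other_receptors]",
    "treatments:",
    "  - name: control",
    "    knocked_down: []",
    "  - name: siRNA_I",
    "    knocked_down: [isoform_I]",
    "  - name: siRNA_ALL",
    "    knocked_down: [isoform_I, isoforms_II_IV]"
  ), path)
  d <- read_design(path)
  expect_equal(d$channels, egfr_design()$channels)
  expect_equal(d$treatments, egfr_design()$treatments)
  expect_equal(read_design("egfr-default")$stimulus, "EGF")
  expect_error(read_design("/nonexistent/design.yaml"), "not found")
})
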