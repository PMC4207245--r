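test_that("measure_pair matches brute-force distances on generated coordinates", {
  h <- build_ideal_helix(9, noise_sd = 0.4, seed = 11)
  for (i in c(1, 3, 5)) {
    m <- measure_pair(h, "A", i)
    expect_equal(m$d_ca, atom_dist(h, i, "CA", i + 4, "CA"), tolerance = 1e-12)
    expect_equal(m$d_o, atom_dist(h, i, "O", i + 4, "O"), tolerance = 1e-12)
    expect_equal(m$d_hbond, atom_dist(h, i, "O", i + 4, "N"),
                 tolerance = 1e-12)
    expect_equal(m$delta, abs(m$d_ca - m$d_o))
  }
  expect_error(measure_pair(h, "A", 6), "missing residue")
  expect_error(measure_pair(h, "B", 1), "missing residue")
})

test_that("delta is invariant under rigid-body motion", {
  h <- build_ideal_helix(12, noise_sd = 0.3, seed = 3)
  base <- measure_pairs(h)
  for (s in 1:5) {
    moved <- rigid_transform(h, seed = s)
    expect_equal(measure_pairs(moved)$delta, base$delta, tolerance = 1e-6)
  }
})

test_that("pair enumeration and helix containment follow the annotation", {
  h <- build_ideal_helix(12)
  p_all <- measure_pairs(h, helix_annotation("A", 1, 12))
  expect_equal(nrow(p_all), 8L)
  expect_true(all(p_all$in_helix))

  p_part <- measure_pairs(h, helix_annotation("A", 1, 6))
  expect_equal(p_part$in_helix, p_part$res_i %in% 1:2)  # straddlers non-helix

  p_short <- measure_pairs(h, helix_annotation("A", 5, 8))
  expect_false(any(p_short$in_helix))  # 4-residue annotation fits no pair

  # numbering gaps make a pair unavailable
  h2 <- build_ideal_helix(12)
  h2$atoms <- h2$atoms[h2$atoms$res_number != 6L, ]
  p_gap <- measure_pairs(h2)
  expect_false(any(p_gap$res_i == 2L | p_gap$res_j == 6L))
})

test_that("every pair is in exactly one of the helix / non-helix populations", {
  h <- build_ideal_helix(20, noise_sd = 0.2, seed = 9)
  p <- measure_pairs(h, helix_annotation("A", c(2, 11), c(8, 16)))
  expect_equal(sum(p$in_helix) + sum(!p$in_helix), nrow(p))
})

test_that("hydrogen-bond correction keeps an ideal helix and trims a broken one", {
  h <- build_ideal_helix(12)
  ann <- helix_annotation("A", 1, 12)
  cr <- correct_helices(h, ann)
  expect_equal(nrow(cr$rejected), 0L)
  expect_equal(cr$helices$start_res, 1L)
  expect_equal(cr$helices$end_res, 12L)
  expect_equal(cr$helices$source, "corrected")

  # displace the last residue by 5 A: its O(i)-N(i+4) partners break
  broken <- build_ideal_helix(16)
  last <- broken$atoms$res_number == 16L
  broken$atoms$x[last] <- broken$atoms$x[last] + 5
  # residue 12's partner (16) moved away: verify independently, then correct
  expect_gt(atom_dist(broken, 12, "O", 16, "N"), 3.6)
  cr2 <- correct_helices(broken, helix_annotation("A", 1, 16))
  expect_true(12L %in% cr2$rejected$res_number)
  expect_true(all(cr2$helices$end_res < 16L | cr2$helices$start_res > 12L))

  # an annotation shorter than the minimum run disappears entirely
  cr3 <- correct_helices(h, helix_annotation("A", 4, 7))
  expect_equal(nrow(cr3$helices), 0L)
})

test_that("correction does not increase the in-helix mean delta on mis-annotated helices", {
  for (seed in 1:6) {
    h <- perturbed_helix(25, n_displaced = 2, shift = 5, seed = seed)
    ann <- helix_annotation("A", 1, 25)
    before <- summarize_deltas(
      dplyr::filter(measure_pairs(h, ann), in_helix), "helix")
    cr <- correct_helices(h, ann)
    after_pairs <- dplyr::filter(measure_pairs(h, cr$helices), in_helix)
    if (nrow(after_pairs) == 0) next
    after <- summarize_deltas(after_pairs, "helix_corrected")
    expect_lte(after$mean_delta, before$mean_delta + 1e-9)
  }
})

test_that("delta summaries use the population standard deviation", {
  p <- tibble::tibble(delta = c(0.1, 0.1, 0.1))
  s <- summarize_deltas(p, "helix")
  expect_equal(s$mean_delta, 0.1)
  expect_equal(s$sd_delta, 0)

  s2 <- summarize_deltas(tibble::tibble(delta = c(0, 0.2)), "helix")
  expect_equal(s2$mean_delta, 0.1)
  expect_equal(s2$sd_delta, 0.1)  # population convention: divide by n

  s0 <- summarize_deltas(tibble::tibble(delta = double(0)), "non_helix")
  expect_equal(s0$n_pairs, 0L)
  expect_true(is.na(s0$mean_delta) && is.na(s0$sd_delta))
})
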