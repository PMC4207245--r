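test_that("wheel positions follow the 100-degree step on a radius-5 circle", {
  w <- wheel_layout(random_sequence(25))
  # residue 1 at 12 o'clock
  expect_equal(c(w$x[1], w$y[1]), c(0, 5), tolerance = 1e-9)
  # residue 19 coincides with residue 1 (18 steps = 5 full turns)
  expect_equal(c(w$x[19], w$y[19]), c(w$x[1], w$y[1]), tolerance = 1e-9)
  # residue 2: independent trig evaluation of r*cos(-10), r*sin(-10)
  expect_equal(c(w$x[2], w$y[2]), c(4.92403876506104, -0.86824088833465),
               tolerance = 1e-9)
  # all residues on the circle
  expect_equal(w$x^2 + w$y^2, rep(25, 25), tolerance = 1e-9)
  # period-18 identity for all indices
  expect_equal(w$x[1:7], w$x[19:25], tolerance = 1e-9)
  expect_equal(w$angle_deg, (90 - 100 * (w$index - 1)) %% 360)
  expect_error(wheel_layout(""), "empty")
})

test_that("residue colour classes follow the scale sign and charge identity", {
  expect_equal(as.character(classify_residue("H")), "hydrophobic_red")
  expect_equal(as.character(classify_residue(c("K", "R"))),
               rep("cationic_darkblue", 2))
  expect_equal(as.character(classify_residue(c("D", "E"))),
               rep("anionic_mediumblue", 2))
  expect_equal(as.character(classify_residue(c("N", "Q"))),
               rep("amide_lightblue", 2))
  expect_equal(as.character(classify_residue("LYS")), "cationic_darkblue")
  expect_error(classify_residue("X"), "unknown residue")
  # red iff positive scale value, over all 20 residues
  sc <- hydrophobicity_scale()
  cls <- classify_residue(sc$aa1)
  expect_equal(cls == "hydrophobic_red", sc$value > 0, ignore_attr = TRUE)
})

test_that("hydrophobic moment matches closed-form cases", {
  m1 <- wheel_moment(wheel_layout("M"))
  expect_equal(unname(m1[c("mx", "my")]), c(0, 0.975), tolerance = 1e-9)
  expect_equal(m1[["magnitude"]], 0.975, tolerance = 1e-9)

  # 18-residue homopolymer: unit vectors 20 degrees apart sum to zero
  m18 <- wheel_moment(wheel_layout(strrep("L", 18)))
  expect_lt(m18[["magnitude"]], 1e-9)
  # 36-mer too (two full wraps)
  expect_lt(wheel_moment(wheel_layout(strrep("K", 36)))[["magnitude"]], 1e-9)
  # length-1 homopolymer magnitude equals |scale value| for every residue
  sc <- hydrophobicity_scale()
  for (aa in sc$aa1) {
    expect_equal(wheel_moment(wheel_layout(aa))[["magnitude"]],
                 abs(sc$value[sc$aa1 == aa]), tolerance = 1e-12)
  }
})

test_that("moment agrees with the brute-force oracle on random sequences", {
  set.seed(202)
  for (i in 1:100) {
    seqs <- random_sequence(sample(3:40, 1))
    w <- wheel_layout(seqs)
    m <- wheel_moment(w)
    o <- moment_oracle(strsplit(seqs, "")[[1]])
    expect_equal(m[["mx"]], o[["mx"]], tolerance = 1e-9)
    expect_equal(m[["my"]], o[["my"]], tolerance = 1e-9)
    expect_equal(m[["magnitude"]], o[["magnitude"]], tolerance = 1e-9)
  }
})

test_that("moment magnitude is invariant under global wheel rotation", {
  set.seed(7)
  for (i in 1:20) {
    seqs <- random_sequence(sample(5:25, 1))
    offset <- runif(1, -360, 360)
    m0 <- wheel_moment(wheel_layout(seqs))
    m1 <- wheel_moment(wheel_layout(seqs, init_angle_deg = 90 + offset))
    expect_equal(m1[["magnitude"]], m0[["magnitude"]], tolerance = 1e-9)
  }
})

test_that("SP1-1 has a much smaller moment than KR-12", {
  sp11 <- hydrophobic_moment(">SP1-1\nRKKRLKLLKRL")
  kr12 <- hydrophobic_moment(">KR-12\nKRIVQRIKDFLR")
  expect_equal(sp11$magnitude, 3.878081964, tolerance = 1e-8)
  expect_equal(kr12$magnitude, 10.05978557, tolerance = 1e-8)
  expect_lt(sp11$magnitude, kr12$magnitude)
})

test_that("RPNR counts charge composition and ignores position", {
  expect_equal(rpnr("RKKRLKLLKRL"), 1)           # 7 cationic, 0 anionic
  expect_equal(rpnr("KRIVQRIKDFLR"), 5 / 6)
  expect_equal(rpnr("KKDD"), 0.5)
  expect_equal(rpnr("DDE"), 0)
  # permutation invariance
  set.seed(31)
  base <- strsplit("KRIVQRIKDFLR", "")[[1]]
  for (i in 1:10) {
    expect_equal(rpnr(sample(base)), 5 / 6)
  }
  # undefined, not zero, without charged residues
  expect_warning(v <- rpnr("GAVLIM"), "undefined")
  expect_true(is.na(v))
  # histidine is not counted as charged
  expect_warning(expect_true(is.na(rpnr("HHHH"))), "undefined")
})

test_that("RPNR separates charge-swapped variants that a charge vector cannot", {
  # An all-cationic hydrophilic face versus the same wheel with one cationic
  # residue moved across the wheel and replaced by an anionic one: the net
  # charge-vector construction can stay the same while the composition, and
  # hence RPNR, changes.
  a <- "KRKVQRVKDFLR"
  a_chars <- strsplit(a, "")[[1]]
  b_chars <- a_chars
  b_chars[a_chars == "D"][1] <- "K"  # variant with no anionic residue
  b <- paste(b_chars, collapse = "")
  expect_equal(rpnr(b), 1)
  expect_lt(rpnr(a), 1)
  expect_equal(sum(strsplit(a, "")[[1]] %in% c("K", "R", "D", "E")),
               sum(strsplit(b, "")[[1]] %in% c("K", "R", "D", "E")))
})

test_that("structure input yields one wheel per annotated helix", {
  seq24 <- strsplit("KLLKKLALKAAKLAKKLLKALAAK", "")[[1]]
  h <- build_ideal_helix(24, sequence = seq24)
  ann <- helix_annotation("A", c(1, 13), c(12, 24))
  ws <- structure_wheels(h, ann)
  expect_named(ws, c("helix1", "helix2"))
  expect_equal(nrow(ws$helix1), 12L)
  expect_equal(ws$helix2$residue, seq24[13:24])
  expect_error(structure_wheels(h, helix_annotation("B", 1, 5)), "no annotated")
})

test_that("custom scales load from two-column text and drive the moment", {
  sc <- hydrophobicity_scale()
  path <- tempfile(fileext = ".txt")
  writeLines(c("# test scale", sprintf("%s %g", sc$aa3, sc$value * 2)), path)
  sc2 <- read_scale(path)
  expect_equal(sort(sc2$aa3), sort(sc$aa3))
  m2 <- wheel_moment(wheel_layout("KRIVQRIKDFLR", scale = sc2))
  m1 <- wheel_moment(wheel_layout("KRIVQRIKDFLR"))
  expect_equal(m2[["magnitude"]], 2 * m1[["magnitude"]], tolerance = 1e-9)
  # missing residues are rejected
  writeLines(sprintf("%s %g", sc$aa3[-1], sc$value[-1]), path)
  expect_error(read_scale(path), "20 residues")
})
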