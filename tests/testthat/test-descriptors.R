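test_that("encoding maps residues to their stored triples, with positions", {
  enc <- encode_peptide("RR")
  expect_equal(nrow(enc), 2L)
  expect_equal(enc$z1, c(5.9227, 5.9227))
  expect_equal(enc$pos, 1:2)
  one <- encode_peptide("A")
  expect_equal(c(one$z1, one$z2, one$z3), c(-3.4535, -0.8314, 0.8710))
  expect_error(encode_peptide(""), "Empty peptide")
  expect_error(encode_peptide("AXG"), "position 2")
})

test_that("mean z-scores agree with hand summation and stay in the convex hull", {
  # hand-summed oracle over the penetratin sequence
  pen_sum <- sum(Z1[strsplit(PEN, "")[[1]]])
  expect_equal(pen_sum, 35.0364, tolerance = 1e-10)
  expect_equal(unname(mean_z(PEN)["z1"]), pen_sum / 16, tolerance = 1e-10)
  expect_equal(round(mean_z(PEN)["z1"], 4), c(z1 = 2.1898))

  expect_equal(unname(mean_z("AG")["z2"]), (-0.8314 + -1.7938) / 2)
  expect_equal(unname(mean_z("KKKK")), c(2.7685, 0.6670, 2.5607),
               ignore_attr = TRUE)

  # convexity: any mean lies within the per-component range of the scale
  rng <- apply(as.matrix(zscale()$scores[, -1]), 2, range)
  for (s in c(PEN, PVEC, "WWDDG", "MM")) {
    m <- mean_z(s)
    expect_true(all(m >= rng[1, ] - 1e-12 & m <= rng[2, ] + 1e-12))
  }
})

test_that("z-scale moment matches the complex-sum oracle and its symmetries", {
  # single residue: modulus of one unit-phase vector
  expect_equal(z_moment("R", component = 1), 5.9227)
  expect_equal(z_moment("D", component = 3), abs(-1.7815))

  # 18 distinct phases at 100 degrees cancel exactly for a homopolymer
  expect_lt(z_moment(strrep("K", 18)), 1e-9)

  # complex-arithmetic oracle on real sequences, all three components
  for (s in c(PEN, PVEC, CYS_PEN)) {
    z <- as.matrix(lookup_z(zscale(), strsplit(s, "")[[1]])[, -1])
    for (comp in 1:3) {
      expect_equal(z_moment(s, component = comp),
                   oracle_moment(z[, comp]), tolerance = 1e-10)
    }
  }

  # invariance under index-origin shift: rotating every phase by a constant
  # leaves the modulus unchanged
  z2 <- as.matrix(lookup_z(zscale(), strsplit(PEN, "")[[1]])[, -1])[, 2]
  ang <- (seq_along(z2) + 7) * 100 * pi / 180
  shifted <- Mod(sum(z2 * exp(1i * ang)))
  expect_equal(z_moment(PEN, component = 2), shifted, tolerance = 1e-9)

  # reversal conjugates the complex sum (phases map to a rigid rotation of
  # their negatives), so the modulus is reversal-invariant exactly
  probe <- "RRRRLLLAAKK"
  rev_probe <- paste(rev(strsplit(probe, "")[[1]]), collapse = "")
  expect_equal(z_moment(probe, component = 1),
               z_moment(rev_probe, component = 1), tolerance = 1e-10)
})

test_that("terminal differences follow the truncation fragments", {
  expect_equal(unname(terminal_difference("RKAAKR", mode = "halves")),
               c(0, 0, 0))
  d <- terminal_difference("RRRAAA", mode = "halves")
  expect_equal(unname(d["z1"]), abs(5.9227 - (-3.4535)))
  # shorter than the cut: whole sequence both sides, with a warning
  expect_warning(
    d4 <- terminal_difference("RKAD", mode = "first_last_5"),
    "whole sequence"
  )
  expect_equal(unname(d4), c(0, 0, 0))
})

test_that("charge composition reproduces the reference peptide counts", {
  pen <- charge_descriptors(PEN)
  expect_equal(c(pen$n_arg, pen$n_lys, pen$n_his), c(3L, 4L, 0L))
  pvec <- charge_descriptors(PVEC)
  expect_equal(c(pvec$n_arg, pvec$n_lys, pvec$n_his), c(4L, 2L, 2L))

  anionic <- charge_descriptors("DDEE")
  expect_equal(anionic$total_charge, -4L)
  expect_equal(anionic$mean_net_charge, -1.0)
  expect_equal(anionic$pos_neg_ratio, 0)

  no_neg <- charge_descriptors("RKH")
  expect_true(is.na(no_neg$pos_neg_ratio))

  # identity: total charge decomposes into the counted residues
  for (s in c(PEN, PVEC, "DDEE", "GGG", "RHDKE")) {
    d <- charge_descriptors(s)
    expect_identical(d$total_charge,
                     (d$n_arg + d$n_lys + d$n_his) - (d$n_asp + d$n_glu))
    expect_identical(d$n_positive, d$n_arg + d$n_lys + d$n_his)
    expect_identical(d$n_negative, d$n_asp + d$n_glu)
  }
})

test_that("hydrophilic ratio reproduces all four reference values", {
  expect_equal(hydrophilic_ratio(PEN), 63)       # 10/16 = 62.5, half-up
  expect_equal(hydrophilic_ratio(CYS_PEN), 59)
  expect_equal(hydrophilic_ratio(PVEC), 44)
  expect_equal(hydrophilic_ratio(CYS_PVEC), 42)
  expect_equal(hydrophilic_ratio("LLLL"), 0)
  # reversal-invariant, as any composition statistic
  expect_equal(hydrophilic_ratio(PEN),
               hydrophilic_ratio(paste(rev(strsplit(PEN, "")[[1]]),
                                       collapse = "")))
})

test_that("steric bulk and net H-bond donation follow the packaged tables", {
  expect_equal(steric_bulk("GGGG"), 0)
  expect_equal(steric_bulk("AAAA"), 1)
  expect_equal(steric_bulk("RW"), 8.5)
  expect_equal(net_hbond_donation("LLLL"), 0)
  # sign convention: pure Asp is purely accepting
  expect_equal(net_hbond_donation("DD"), -4)
  # brute-force per-residue table walk
  hb <- utils::read.csv(system.file("extdata", "sidechain_hbonds.csv",
                                    package = "pepqsar"))
  for (s in c(PEN, PVEC, "STYW")) {
    chars <- strsplit(s, "")[[1]]
    manual <- mean(vapply(chars, function(ch) {
      row <- hb[hb$residue == ch, ]
      row$donors - row$acceptors
    }, numeric(1)))
    expect_equal(net_hbond_donation(s), manual)
  }
})

test_that("descriptor table has a stable schema and id-independent values", {
  dup <- tibble::tibble(id = c("a", "b"), sequence = c(PEN, PEN))
  desc <- peptide_descriptors(dup)
  expect_equal(as.numeric(desc[1, -(1:2)]), as.numeric(desc[2, -(1:2)]))

  desc4 <- peptide_descriptors(
    tibble::tibble(id = c("Pen", "Cys-Pen", "pVEC", "Cys-pVEC"),
                   sequence = c(PEN, CYS_PEN, PVEC, CYS_PVEC))
  )
  expect_equal(desc4$length, c(16L, 17L, 18L, 19L))
  expect_equal(desc4$n_arg, c(3L, 3L, 4L, 4L))
  expect_equal(desc4$n_lys, c(4L, 4L, 2L, 2L))
  expect_equal(desc4$n_his, c(0L, 0L, 2L, 2L))
  expect_equal(desc4$hydrophilic_ratio, c(63, 59, 44, 42))

  # schema is fixed across calls and inputs
  short <- suppressWarnings(peptide_descriptors("GG"))
  expect_identical(names(desc4), names(short[, names(desc4)]))
  m <- descriptor_matrix(desc4)
  expect_false("pos_neg_ratio" %in% colnames(m))
  expect_equal(rownames(m), desc4$id)
})
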