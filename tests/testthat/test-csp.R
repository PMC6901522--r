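test_that("combined perturbation follows the scaled-quadrature formula", {
  expect_identical(csp_combine(0, 0), 0)
  expect_equal(csp_combine(0.03, 0.20), 0.05)
  # depends only on displacement magnitudes
  expect_equal(csp_combine(-0.03, 0.20), 0.05)
  expect_equal(csp_combine(0.03, -0.20), 0.05)
  set.seed(1)
  dh <- rnorm(50, 0, 0.1); dn <- rnorm(50, 0, 0.5)
  expect_equal(csp_combine(dh, dn), csp_combine(-dh, -dn))
  expect_equal(csp_combine(dh, dn), sqrt(dh^2 + (dn / 5)^2))
})

test_that("per-residue CSP tables behave as displacements b minus a", {
  a <- toy_peaklist()
  expect_equal(compute_csp(a, a)$delta_NH, rep(0, 3))

  b <- a
  b$delta_H[b$label == "H49N-H"] <- b$delta_H[b$label == "H49N-H"] + 0.03
  b$delta_N[b$label == "H49N-H"] <- b$delta_N[b$label == "H49N-H"] + 0.20
  tab <- compute_csp(a, b)
  expect_equal(tab$delta_NH[tab$label == "H49N-H"], 0.05)
  expect_equal(tab$delta_NH[tab$label != "H49N-H"], c(0, 0))
  # magnitude symmetric under argument swap
  expect_equal(abs(compute_csp(b, a)$delta_NH), abs(tab$delta_NH))

  other <- toy_peaklist(labels = "G99N-H", dN = 110, dH = 8.5)
  expect_error(compute_csp(a, other), "no common")
})

test_that("alignment to a reference peak removes global offsets", {
  a <- toy_peaklist(name = "ref")
  # identity: already coincident
  out <- align_to_reference(list(a, a), "W77N-H")
  expect_equal(attr(out, "offsets"), matrix(0, 2, 2), ignore_attr = TRUE)
  expect_equal(out[[2]]$delta_H, a$delta_H)

  # a globally shifted copy aligns back to zero CSP everywhere
  b <- shift_peaklist(a, dH = 0.02, dN = 0.10, name = "shifted")
  out <- align_to_reference(list(a, b), "W77N-H")
  expect_equal(max(compute_csp(out[[1]], out[[2]])$delta_NH), 0,
               tolerance = 1e-12)

  # reference CSP is exactly zero for any aligned pair
  set.seed(3)
  c2 <- a
  c2$delta_H <- a$delta_H + rnorm(3, 0, 0.05)
  c2$delta_N <- a$delta_N + rnorm(3, 0, 0.2)
  out <- align_to_reference(list(a, b, c2), "W77N-H")
  for (i in 2:3) {
    tab <- compute_csp(out[[1]], out[[i]])
    expect_equal(tab$delta_NH[tab$label == "W77N-H"], 0)
  }

  no_ref <- toy_peaklist(labels = c("E34N-H", "H49N-H"),
                         dN = c(118.2, 120.5), dH = c(8.1, 8.2),
                         name = "pH 8")
  expect_error(align_to_reference(list(a, no_ref), "W77N-H"),
               "pH 8")
})

test_that("a common additive shift of both spectra leaves aligned CSPs unchanged", {
  set.seed(4)
  a <- toy_peaklist()
  b <- shift_peaklist(a, dH = 0.01, dN = 0.05)
  b$delta_H <- b$delta_H + c(0.03, -0.02, 0)  # real per-residue changes
  base <- align_to_reference(list(a, b), "W77N-H")
  base_csp <- compute_csp(base[[1]], base[[2]])$delta_NH
  for (off in list(c(0.5, 2), c(-0.1, -1))) {
    a2 <- shift_peaklist(a, off[1], off[2])
    b2 <- shift_peaklist(b, off[1], off[2])
    out <- align_to_reference(list(a2, b2), "W77N-H")
    expect_equal(compute_csp(out[[1]], out[[2]])$delta_NH, base_csp)
  }
})

test_that("Tukey-fence binning matches the hand-computed quantile oracle", {
  # type-7 quartiles of {0.01, 0.02, 0.03, 0.04}:
  # Q1 = 0.0175, Q3 = 0.0325, IQR = 0.015, fence b = 0.0325 + 1.5*0.015
  ref <- c(0.01, 0.02, 0.03, 0.04)
  b_exp <- 0.0325 + 1.5 * 0.015
  res <- bin_csp(c(0, 0.04, 0.10), reference_values = ref)
  expect_equal(res$scheme$first_bound, b_exp)
  expect_equal(res$map$bin, c(1L, 1L, 2L))  # 0.10 in (b, 2b]
  # boundaries are exact multiples of the first bound, last bin open
  expect_equal(res$scheme$bounds[1:9], b_exp * 1:9)
  expect_identical(res$scheme$bounds[10], Inf)

  # all values zero -> everything in bin 1
  expect_true(all(bin_csp(rep(0, 5), reference_values = ref)$map$bin == 1L))
  # value beyond 10 b clamps into the open top bin
  expect_equal(bin_csp(20 * b_exp, reference_values = ref)$map$bin, 10L)
  # right-closed intervals: exactly b is still bin 1
  expect_equal(bin_csp(b_exp, reference_values = ref)$map$bin, 1L)

  # degenerate all-zero reference asks for an explicit bound
  expect_error(bin_csp(c(0.1), reference_values = rep(0, 6)),
               "explicit first_bound")
  expect_equal(bin_csp(0.1, first_bound = 0.02)$map$bin, 5L)
})

test_that("bin index is non-decreasing in the perturbation and fence dominates Q3", {
  set.seed(6)
  for (rep in 1:20) {
    ref <- abs(rnorm(15, 0.02, 0.01))
    v <- sort(abs(rnorm(30, 0.05, 0.05)))
    res <- bin_csp(v, reference_values = ref)
    expect_true(all(diff(res$map$bin) >= 0))
    q <- quantile(ref, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    expect_gte(res$scheme$first_bound, q[3])
    expect_gte(q[3], q[2])
  }
})

test_that("bins written to B-factors round-trip through a PDB file", {
  set.seed(8)
  nm <- c("N", "CA", "C", "O")
  xyz <- matrix(rnorm(4 * 5 * 3, sd = 5), ncol = 3)
  mod <- toy_model(xyz, name = rep(nm, 5), resno = rep(47:51, each = 4))
  ens <- read_ensemble(write_toy_pdb(list(mod)))

  vals <- structure(
    data.frame(label = sprintf("A%dN-H", c(47, 49, 50, 51)),
               residue_number = c(47L, 49L, 50L, 51L),
               delta_NH = c(0.001, 0.50, 0.02, 0.12)),
    class = c("csp_table", "data.frame"))
  vals$residue_type <- "A"
  binning <- bin_csp(vals, first_bound = 0.05)
  pdb_out <- tempfile(fileext = ".pdb")
  col_out <- tempfile(fileext = ".tsv")
  tab <- map_bins_to_structure(binning, ens, pdb_file = pdb_out,
                               color_file = col_out)
  # residue 49 in the top bin, residue 48 unassigned -> sentinel -1 / black
  expect_equal(tab$bin[tab$resno == 49], 10L)
  expect_equal(tab$bin[tab$resno == 48], -1L)
  expect_equal(tab$color[tab$resno == 48], "black")

  back <- bio3d::read.pdb(pdb_out, verbose = FALSE)
  b_by_res <- tapply(back$atom$b, back$atom$resno, unique)
  expect_equal(as.numeric(b_by_res[as.character(c(47, 49, 50, 51))]),
               as.numeric(binning$map$bin))
  expect_equal(unname(b_by_res[["48"]]), -1)
  col_tab <- read.delim(col_out)
  expect_equal(col_tab$bin, tab$bin)
})

test_that("condition comparison issues perturbed/unperturbed verdicts", {
  a <- toy_peaklist()
  expect_equal(compare_conditions(a, a)$verdict, "unperturbed")

  b <- a
  b$delta_H[2] <- b$delta_H[2] + 0.1
  cmp <- compare_conditions(a, b, threshold = 0.02)
  expect_equal(cmp$verdict, "perturbed")
  expect_equal(cmp$exceeding, a$label[2])

  # calcium-mimic dataset: every displacement constructed below threshold
  set.seed(10)
  cal <- a
  cal$delta_H <- a$delta_H + runif(3, -0.002, 0.002)
  cal$delta_N <- a$delta_N + runif(3, -0.005, 0.005)
  expect_equal(compare_conditions(a, cal, threshold = 0.02)$verdict,
               "unperturbed")
})
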