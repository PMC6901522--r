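# Shared fixture builders; everything is generated in code.

toy_peaklist <- function(labels = c("E34N-H", "H49N-H", "W77N-H"),
                         dN = c(118.2, 120.5, 129.8),
                         dH = c(8.10, 8.20, 10.05),
                         height = NA_real_,
                         name = "toy", pH = NA_real_) {
  peaklist(labels, delta_N = dN, delta_H = dH, height = height,
           condition = condition(name, pH = pH))
}

# shift an entire peak list by a constant (referencing offset)
shift_peaklist <- function(pl, dH = 0, dN = 0, name = NULL, pH = NULL) {
  pl2 <- pl
  pl2$delta_H <- pl$delta_H + dH
  pl2$delta_N <- pl$delta_N + dN
  cond <- attr(pl, "condition")
  if (!is.null(name)) cond$name <- name
  if (!is.null(pH)) cond$pH <- pH
  attr(pl2, "condition") <- cond
  pl2
}

# minimal multi-model PDB text
toy_pdb_text <- function(models) {
  fmt <- function(m, serial, name, resno, x, y, z) {
    sprintf("ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
            serial, name, "ALA", resno, x, y, z, substr(name, 1, 1))
  }
  out <- character()
  for (k in seq_along(models)) {
    m <- models[[k]]
    out <- c(out, sprintf("MODEL     %4d", k))
    for (i in seq_len(nrow(m$xyz)))
      out <- c(out, fmt(m, i, m$name[i], m$resno[i],
                        m$xyz[i, 1], m$xyz[i, 2], m$xyz[i, 3]))
    out <- c(out, "ENDMDL")
  }
  c(out, "END")
}

write_toy_pdb <- function(models, file = tempfile(fileext = ".pdb")) {
  writeLines(toy_pdb_text(models), file)
  file
}

toy_model <- function(xyz, name = rep("CA", nrow(xyz)),
                      resno = seq_len(nrow(xyz))) {
  list(xyz = xyz, name = name, resno = resno)
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         nrow = 3, byrow = TRUE)
}

# Henderson-Hasselbalch perturbation curve relative to the first pH
hh_curve <- function(pKa, amplitude, pH = c(5.5, 6, 6.25, 6.5, 7, 7.4, 8),
                     label = "") {
  y <- amplitude / (1 + 10^(pKa - pH))
  titration_curve(pH, y - y[1], label = label)
}

# location of optional downloaded validation inputs (see README)
validation_file <- function(name) testthat::test_path("validation", name)
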