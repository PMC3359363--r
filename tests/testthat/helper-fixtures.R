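# Fixture builders and independent brute-force oracles used across tests.
# Oracles deliberately re-derive results by the most direct method available
# (character scans, exhaustive loops, pair counting) so they stay independent
# of the package implementation they check.

AAS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_sequence <- function(n, alphabet = AAS) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# --- PSSM fixture in blastpgp ASCII layout ------------------------------
# percentages: integer matrix (positions x 20) in blastpgp column order
blast_order <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

make_pssm_text <- function(percentages, residues = NULL) {
  stopifnot(ncol(percentages) == 20L)
  if (is.null(residues)) residues <- rep("A", nrow(percentages))
  header <- c(
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    "",
    paste0("           ", paste(sprintf("%3s", blast_order), collapse = " "),
           "  ", paste(sprintf("%3s", blast_order), collapse = " "))
  )
  body <- vapply(seq_len(nrow(percentages)), function(i) {
    paste0(sprintf("%5d %s ", i, residues[i]),
           paste(sprintf("%3d", rep(0L, 20L)), collapse = " "), "  ",
           paste(sprintf("%3d", percentages[i, ]), collapse = " "),
           "  0.50      0.10")
  }, character(1))
  c(header, body, "", "                      K         Lambda")
}

# --- minimal PDB writer -------------------------------------------------
pdb_atom_line <- function(serial, elety, resid, chain, resno, xyz) {
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial, paste0(" ", elety), resid, chain, resno,
          xyz[1], xyz[2], xyz[3])
}

write_mini_pdb <- function(path, resno, ca, cb = NULL, resid = NULL,
                           chain = "A") {
  if (is.null(resid)) resid <- rep("ALA", length(resno))
  lines <- character(0)
  serial <- 0L
  for (i in seq_along(resno)) {
    serial <- serial + 1L
    lines <- c(lines, pdb_atom_line(serial, "CA", resid[i], chain, resno[i], ca[i, ]))
    if (!is.null(cb) && !is.na(cb[i, 1])) {
      serial <- serial + 1L
      lines <- c(lines, pdb_atom_line(serial, "CB", resid[i], chain, resno[i], cb[i, ]))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

write_multimodel_pdb <- function(path, coords, resno = NULL) {
  # coords: S x N x 3
  if (is.null(resno)) resno <- seq_len(dim(coords)[2])
  lines <- character(0)
  for (s in seq_len(dim(coords)[1])) {
    lines <- c(lines, sprintf("MODEL     %4d", s))
    for (i in seq_along(resno)) {
      lines <- c(lines, pdb_atom_line(i, "CA", "ALA", "A", resno[i], coords[s, i, ]))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

# --- Stride fixture -----------------------------------------------------
make_stride_text <- function(codes, resno = seq_along(codes), resid = "ALA") {
  full_names <- c(H = "AlphaHelix", G = "310Helix", I = "PiHelix",
                  E = "Strand", B = "Bridge", b = "Bridge",
                  T = "Turn", C = "Coil", S = "Bend")
  c("REM  --------------- Secondary structure summary -------------------",
    sprintf("ASG  %3s A %4d %4d    %s    %-12s   -60.00    -40.00     100.0",
            resid, resno, seq_along(codes), codes, full_names[codes]))
}

# --- independent oracles ------------------------------------------------

# linear character scan for candidate C/S/T sites with a full -3..+4 window
oracle_scan_sites <- function(seq_string) {
  res <- strsplit(seq_string, "")[[1]]
  out <- integer(0)
  for (i in seq_along(res)) {
    if (res[i] %in% c("C", "S", "T") && i - 3 >= 1 && i + 4 <= length(res)) {
      out <- c(out, i)
    }
  }
  out
}

# term-by-term entropy summation
oracle_entropy <- function(p) {
  s <- 0
  for (pj in p) if (pj > 0) s <- s - pj * log(pj)
  s
}

# sort-free fractional rank: strictly-higher entropies + half ties over n-1
oracle_rank <- function(entropies, target_idx) {
  others <- entropies[-target_idx]
  (sum(others > entropies[target_idx]) + 0.5 * sum(others == entropies[target_idx])) /
    (length(entropies) - 1)
}

# outward scan for the nearest complementary-group residue
oracle_classify <- function(groups, idx) {
  g <- groups[idx]
  if (is.na(g) || g == "other") return(list(bin = "other", junction_distance = NA_real_))
  want <- switch(g, helix = "loop", sheet = "loop", loop = c("helix", "sheet"))
  n <- length(groups)
  found <- NULL
  for (d in seq_len(n)) {
    hits <- character(0)
    for (j in c(idx - d, idx + d)) {
      if (j >= 1 && j <= n && !is.na(groups[j]) && groups[j] %in% want) {
        hits <- c(hits, groups[j])
      }
    }
    if (length(hits)) { found <- list(d = d, hits = hits); break }
  }
  if (is.null(found)) {
    bin <- switch(g, helix = "mid-AH", sheet = "mid-BS", loop = "mid-L")
    return(list(bin = bin, junction_distance = Inf))
  }
  d <- found$d
  if (d > 2) {
    bin <- switch(g, helix = "mid-AH", sheet = "mid-BS", loop = "mid-L")
  } else if (g == "helix") {
    bin <- "AH/L-junction"
  } else if (g == "sheet") {
    bin <- "BS/L-junction"
  } else {
    bin <- if ("sheet" %in% found$hits) "BS/L-junction" else "AH/L-junction"
  }
  list(bin = bin, junction_distance = d)
}

# Mann-Whitney pair-counting AUC (ties get half credit)
oracle_auc_pairs <- function(values, labels, higher_is_positive = TRUE) {
  pos <- values[labels]; neg <- values[!labels]
  tot <- 0
  for (p in pos) for (q in neg) {
    cmp <- if (higher_is_positive) sign(p - q) else sign(q - p)
    tot <- tot + (cmp + 1) / 2
  }
  tot / (length(pos) * length(neg))
}

random_extein <- function(id = "rnd", n = 200) {
  extein_record(id, random_sequence(n))
}
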