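# Shared fixtures and independent oracles. Oracles are deliberately
# naive (double loops, factorial formulas, pairwise comparisons) so they
# stay independent of the vectorized implementation paths they check.

# -- PDB text fixtures -------------------------------------------------

pdb_atom_line <- function(serial, name, altloc, resname, chain, resno,
                          x, y, z, occ = 1, elem = substr(name, 1, 1),
                          record = "ATOM") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, altloc, resname, chain, resno,
          x, y, z, occ, 0, elem)
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# one-CA-per-residue structure from a coordinate matrix
structure_from_xyz <- function(xyz, id = "toy", chain = "A") {
  xyz <- as.matrix(xyz)
  new_structure(id, data.frame(
    chain = chain, resno = seq_len(nrow(xyz)), ins = "", resid = "ALA",
    elety = "CA", elesy = "C",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    o = 1, alt = "", stringsAsFactors = FALSE))
}

# random toy structure: n_res residues, 1..max_atoms atoms each,
# centred near the origin
random_structure <- function(n_res, max_atoms = 4, spread = 10,
                             id = "rnd", chain = "A") {
  rows <- do.call(rbind, lapply(seq_len(n_res), function(i) {
    k <- sample.int(max_atoms, 1)
    centre <- runif(3, -spread, spread)
    data.frame(chain = chain, resno = i, ins = "", resid = "ALA",
               elety = paste0("C", seq_len(k)), elesy = "C",
               x = centre[1] + rnorm(k), y = centre[2] + rnorm(k),
               z = centre[3] + rnorm(k), o = 1, alt = "",
               stringsAsFactors = FALSE)
  }))
  new_structure(id, rows)
}

# -- oracles -----------------------------------------------------------

# exhaustive all-atom-pairs contact oracle
oracle_contacts <- function(receptor, ligand, cutoff = 3.5) {
  ra <- receptor$atoms
  la <- ligand$atoms
  hit <- logical(nrow(receptor$residues))
  for (i in seq_len(nrow(ra))) {
    for (j in seq_len(nrow(la))) {
      d <- sqrt((ra$x[i] - la$x[j])^2 + (ra$y[i] - la$y[j])^2 +
                  (ra$z[i] - la$z[j])^2)
      if (d <= cutoff) hit[ra$res_idx[i]] <- TRUE
    }
  }
  receptor$residues$res_id[hit]
}

# minimum interatomic distance by double loop
oracle_min_dist <- function(a_xyz, b_xyz) {
  best <- Inf
  for (i in seq_len(nrow(a_xyz)))
    for (j in seq_len(nrow(b_xyz)))
      best <- min(best, sqrt(sum((a_xyz[i, ] - b_xyz[j, ])^2)))
  best
}

# factorial evaluation of the hypergeometric pmf, independent of dhyper
oracle_hyper_pmf <- function(x, N, M, K) {
  if (x < max(0, K + M - N) || x > min(K, M)) return(0)
  choose(M, x) * choose(N - M, K - x) / choose(N, K)
}

# Mann-Whitney AUC: concordant pairs plus half ties
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# per-residue recount of a RIF profile by double loop
oracle_rif_counts <- function(contact_sets, universe) {
  counts <- setNames(integer(length(universe)), universe)
  for (cs in contact_sets)
    for (id in cs)
      counts[id] <- counts[id] + 1L
  counts
}
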