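# small graph fixtures -------------------------------------------------

path_net <- function(n) contact_network(n, cbind(seq_len(n - 1), 2:n))

cycle_net <- function(n) contact_network(n, rbind(cbind(seq_len(n - 1), 2:n),
                                                  c(n, 1)))

complete_net <- function(n) contact_network(n, t(utils::combn(n, 2)))

star_net <- function(n) contact_network(n, cbind(1L, 2:n))

# two disjoint k-cliques
two_cliques_net <- function(k) {
  e1 <- t(utils::combn(k, 2))
  contact_network(2L * k, rbind(e1, e1 + k))
}

edgeless_net <- function(n) contact_network(n)

random_net <- function(n, p = 0.4, seed = 1) {
  set.seed(seed)
  all_e <- t(utils::combn(n, 2))
  keep <- runif(nrow(all_e)) < p
  if (!any(keep)) keep[1] <- TRUE
  contact_network(n, all_e[keep, , drop = FALSE])
}

permute_net <- function(net, perm) {
  contact_network(net$n_nodes, cbind(perm[net$edges[, 1]],
                                     perm[net$edges[, 2]]))
}

# minimal PDB text fixtures ---------------------------------------------

pdb_atom_line <- function(serial, resno, x, y, z, alt = " ", elety = "CA") {
  sprintf("ATOM  %5d %4s%s%3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial, sprintf(" %-3s", elety), alt, "GLY", resno, x, y, z)
}

pdb_two_residues <- function() {
  c(pdb_atom_line(1, 1, 0, 0, 0), pdb_atom_line(2, 2, 0, 0, 5), "END")
}

pdb_two_models <- function() {
  c("MODEL        1",
    pdb_atom_line(1, 1, 0, 0, 0), pdb_atom_line(2, 2, 0, 0, 5),
    "ENDMDL",
    "MODEL        2",
    pdb_atom_line(3, 1, 1, 1, 1), pdb_atom_line(4, 2, 1, 1, 6),
    pdb_atom_line(5, 3, 1, 1, 9),
    "ENDMDL", "END")
}

pdb_altloc <- function() {
  c(pdb_atom_line(1, 1, 0, 0, 0, alt = "A"),
    pdb_atom_line(2, 1, 9, 9, 9, alt = "B"),
    "END")
}

# small planted dataset shared by the learning tests --------------------

planted_small <- function(seed = 11, n_per_class = 20) {
  planted_multiview_dataset(synth_spec(n_per_class = n_per_class,
                                       seed = seed))
}

# independent oracles ---------------------------------------------------

# Mann-Whitney pair-counting AUC (ties count 1/2)
auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == -1]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# union-find connected-component count
components_uf <- function(net) {
  parent <- seq_len(net$n_nodes)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(net$edges)) for (r in seq_len(nrow(net$edges))) {
    a <- find(net$edges[r, 1]); b <- find(net$edges[r, 2])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_len(net$n_nodes), find, integer(1))))
}
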