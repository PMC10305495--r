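# small in-code fixtures shared across tests

write_dt_file <- function(rows, path = tempfile(fileext = ".tsv"),
                          extra_cols = TRUE) {
  header <- c("drug_id", "drug_name", "target_accession", "organism")
  if (extra_cols) header <- c(header, "smiles", "group")
  writeLines(c(paste(header, collapse = "\t"),
               vapply(rows, paste, character(1), collapse = "\t")), path)
  path
}

write_ppi_file <- function(pairs, path = tempfile(fileext = ".tsv")) {
  writeLines(c("accession_a\taccession_b",
               vapply(pairs, paste, character(1), collapse = "\t")), path)
  path
}

# a path graph A - B - C as an interactome
path_abc <- function() {
  interactome(edges = rbind(c("A", "B"), c("B", "C")))
}

# star with given center and leaves
star_net <- function(center = "C0", leaves = paste0("L", 1:4)) {
  interactome(edges = cbind(center, leaves))
}

# one target with 9 neighbors and 9 extra neighbor-neighbor edges:
# 10 nodes, 18 edges in the induced neighborhood
ten_node_fixture <- function() {
  nb <- sprintf("N%d", 1:9)
  ed <- rbind(cbind("T", nb),
              cbind(nb, nb[c(2:9, 1)]))
  interactome(edges = ed)
}

# toy drug-target ecosystem from the construction example:
# D1 -> T (neighbors N1, N2), D2 -> N1
toy_ecosystem <- function() {
  net <- interactome(edges = rbind(c("T", "N1"), c("T", "N2")))
  targets <- data.frame(
    drug_id = c("D1", "D2"), target = c("T", "N1"),
    organism = c("HUMAN", "HUMAN"), stringsAsFactors = FALSE)
  class(targets) <- c("drug_target_table", "data.frame")
  drugs <- data.frame(drug_id = c("D1", "D2"),
                      name = c("Drug 1", "Drug 2"),
                      smiles = NA_character_, group = NA_character_,
                      stringsAsFactors = FALSE)
  list(net = net, targets = targets, drugs = drugs)
}
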