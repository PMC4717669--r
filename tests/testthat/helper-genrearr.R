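## shared helpers; the pair generators live in the package itself
## (enumerate_structure_pairs, random_structure_pair)

enum_small_pairs <- function(max_occ = 4) enumerate_structure_pairs(max_occ)

random_small_pair <- function(total_occ = 6) random_structure_pair(total_occ)

## aliases for internal machinery the white-box tests poke at
eng_new <- genrearr:::eng_new
step1 <- genrearr:::step1
step2 <- genrearr:::step2
engine_components <- genrearr:::engine_components
comp_length <- genrearr:::comp_length
classify_component <- genrearr:::classify_component
cg_components <- genrearr:::cg_components
comp_is_final <- genrearr:::comp_is_final
cg_edges_of <- genrearr:::cg_edges_of
op_cut <- genrearr:::op_cut
op_join <- genrearr:::op_join
op_dcj <- genrearr:::op_dcj
op_sesqui <- genrearr:::op_sesqui
op_delete_region <- genrearr:::op_delete_region
op_insert_region <- genrearr:::op_insert_region
adj_key <- genrearr:::adj_key
ext_head <- genrearr:::ext_head
ext_tail <- genrearr:::ext_tail
ext_gene <- genrearr:::ext_gene
split_adj <- genrearr:::split_adj
enumerate_moves <- genrearr:::enumerate_moves
apply_move <- genrearr:::apply_move
count_special_circles <- genrearr:::count_special_circles
special_runs <- genrearr:::special_runs
par_index <- genrearr:::par_index
relabel_matched <- genrearr:::relabel_matched
signed_tokens <- genrearr:::signed_tokens
gene_family <- genrearr:::gene_family
gene_paralog <- genrearr:::gene_paralog
free_extremities <- genrearr:::free_extremities
universe_distance_matrix <- genrearr:::universe_distance_matrix
iddfs_min_ops <- genrearr:::iddfs_min_ops
compute_invariants <- genrearr::compute_invariants

table1_path <- function() {
  system.file("extdata", "aconoidasida_mito.tsv", package = "genrearr")
}

read_table1 <- function() {
  tab <- utils::read.delim(table1_path(), stringsAsFactors = FALSE)
  structures <- lapply(seq_len(nrow(tab)), function(i) {
    txt <- paste0(tab$gene_order[i], " (", tab$topology[i], ")")
    parse_structure(txt, dialect = "table1", name = tab$species[i])
  })
  names(structures) <- tab$species
  structures
}
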