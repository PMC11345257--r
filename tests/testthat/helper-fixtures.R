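# Small fixtures built in code.

# A bare toy genome: n genes on one contig, length 100 bp, 20 bp gaps.
make_toy_genome <- function(n, contig = "c1", strands = NULL,
                            circular = FALSE, prefix = "g") {
  if (is.null(strands)) strands <- rep("+", n)
  start <- seq(1L, by = 120L, length.out = n)
  genome_annotation(
    data.frame(gene_id = paste0(prefix, seq_len(n)),
               protein_id = paste0("p", seq_len(n)),
               contig_id = contig, start = start, end = start + 99L,
               strand = strands, stringsAsFactors = FALSE),
    circular = setNames(circular, contig))
}

# One toy annotation written in all three dialects.
toy_gff3_text <- c(
  "##gff-version 3",
  "c1\ttest\tgene\t1\t300\t.\t+\t.\tID=gene-g1;locus_tag=g1",
  "c1\ttest\tCDS\t1\t300\t.\t+\t0\tID=cds-p1;Parent=gene-g1;protein_id=p1;product=alpha",
  "c1\ttest\tgene\t400\t700\t.\t-\t.\tID=gene-g2;locus_tag=g2",
  "c1\ttest\tCDS\t400\t700\t.\t-\t0\tID=cds-p2;Parent=gene-g2;protein_id=p2;product=beta",
  "c1\ttest\tCDS\t800\t1000\t.\t+\t0\tID=cds-p3;protein_id=p3;product=orphan")

toy_tsv_text <- c(
  "gene_id\tcontig\tstart\tend\tstrand\tprotein_id\tproduct",
  "g1\tc1\t1\t300\t+\tp1\talpha",
  "g2\tc1\t400\t700\t-\tp2\tbeta",
  "cds-p3\tc1\t800\t1000\t+\tp3\torphan")

toy_genbank_text <- c(
  "LOCUS       c1                 1200 bp    DNA     linear   BCT 01-JAN-2024",
  "DEFINITION  toy record.",
  "FEATURES             Location/Qualifiers",
  "     source          1..1200",
  "                     /organism=\"toy\"",
  "     CDS             1..300",
  "                     /locus_tag=\"g1\"",
  "                     /protein_id=\"p1\"",
  "                     /product=\"alpha\"",
  "     CDS             complement(400..700)",
  "                     /locus_tag=\"g2\"",
  "                     /protein_id=\"p2\"",
  "                     /product=\"beta\"",
  "     CDS             800..1000",
  "                     /locus_tag=\"cds-p3\"",
  "                     /protein_id=\"p3\"",
  "                     /product=\"orphan\"",
  "ORIGIN",
  "//")

write_fixture <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Domain-hit rows in the package dialect.
hit_row <- function(protein_id, tool, label, hit_class = NA_character_) {
  data.frame(protein_id = protein_id, tool = tool, label = label,
             hit_class = hit_class, start = NA_integer_, end = NA_integer_,
             score = NA_real_, stringsAsFactors = FALSE)
}

# A small random genome with randomly planted features, for property tests.
random_sim_genome <- function(seed) {
  set.seed(seed * 7L)
  args <- list(seed = seed,
               n_contigs = sample(1:3, 1),
               genes_per_contig = sample(c(500, 700, 900), 1),
               n_planted_puls = sample(0:3, 1),
               n_dispersed_pathway_genes = sample(2:4, 1),
               min_dispersion_distance = 60,
               n_decoy_pairs = sample(0:2, 1),
               n_lone_susc = sample(0:2, 1),
               n_decoy_cazymes = sample(0:4, 1))
  do.call(sim_genome, args)
}
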