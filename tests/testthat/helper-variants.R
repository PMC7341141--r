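# Row builder matching the layout of read_annotated_variants().
mkvar <- function(pos, effects, gene = NA_character_, chrom = "chr1",
                  ref = "A", alt = "G", deleterious = NA) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             variant_class = if (nchar(ref) == 1 && nchar(alt) == 1)
               "SNP" else "indel",
             gene_id = gene, effects = effects, deleterious = deleterious,
             stringsAsFactors = FALSE)
}

mkgenes <- function(ids, starts, ends, chrom = "chr1") {
  data.frame(gene_id = ids, chrom = chrom, start = starts, end = ends,
             strand = "+", stringsAsFactors = FALSE)
}

mkelems <- function(starts, ends, kinds, chrom = "chr1") {
  data.frame(element_id = paste0("e", seq_along(starts)), chrom = chrom,
             start = starts, end = ends, kind = kinds,
             stringsAsFactors = FALSE)
}
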