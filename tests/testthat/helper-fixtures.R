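# fixture builders shared across test files; everything is generated in
# code so no binary or large files ship with the package

write_test_vcf <- function(records, path = tempfile(fileext = ".vcf")) {
  # records: data.frame with chrom, pos, ref, alt (alt may be "A,ACGTT")
  header <- c("##fileformat=VCFv4.2",
              "##contig=<ID=1>",
              paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", sep = "\t"))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                  records$chrom, records$pos, records$ref, records$alt)
  writeLines(c(header, body), path)
  path
}

write_test_maf <- function(records, path = tempfile(fileext = ".maf")) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# deletion records straight from a length vector, bypassing file parsing
records_from_lengths <- function(lengths, tumor_id) {
  data.frame(tumor_id = tumor_id, chrom = "1",
             pos = seq_along(lengths), ref_len = lengths + 1L,
             alt_len = 1L, deletion_length = as.integer(lengths),
             frameshift = lengths %% 3L != 0L, stringsAsFactors = FALSE)
}

# minimal spatial cell table from coordinate vectors
spatial_table <- function(mac_xy, cd8_xy, dra = NULL, cd74 = NULL,
                          sample_id = "S1") {
  nm <- nrow(mac_xy); nc <- nrow(cd8_xy)
  if (is.null(dra)) dra <- rep(1, nm)
  if (is.null(cd74)) cd74 <- rep(1, nm)
  out <- data.frame(
    cell_id = sprintf("c%03d", seq_len(nm + nc)),
    sample_id = sample_id,
    x_um = c(mac_xy[, 1], cd8_xy[, 1]),
    y_um = c(mac_xy[, 2], cd8_xy[, 2]),
    cell_type = c(rep("Macrophage", nm), rep("CD8T", nc)),
    stringsAsFactors = FALSE, check.names = FALSE)
  out[["HLA-DRA"]] <- c(dra, rep(0, nc))
  out[["CD74"]] <- c(cd74, rep(0, nc))
  out
}

# the enumerable 3-macrophage / 1-CD8 configuration: one APC-like
# macrophage at the origin, CD8 5 um away; exact permutation p = 1/3
enumerable_spatial_config <- function() {
  spatial_table(mac_xy = cbind(c(0, 100, 200), c(0, 0, 0)),
                cd8_xy = cbind(5, 0),
                dra = c(1, 0, 0), cd74 = c(1, 0, 0))
}
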