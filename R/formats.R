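#' @include accessors.R
NULL

#' Read one genome bundle (GFF3 + protein/CDS FASTA)
#'
#' Ingests `gene` features from a GFF3 file and attaches the protein and
#' CDS sequence of every gene by its `ID` attribute. mRNA/exon children are
#' ignored: the comparative analyses operate on gene order, and clade gene
#' structures are handled by the gene-model functions. Coordinates are kept
#' in the GFF3 convention (1-based, inclusive).
#'
#' @param gff_path path to a GFF3 file with `gene` features.
#' @param protein_fasta path to the protein FASTA (headers = gene IDs).
#' @param cds_fasta path to the CDS FASTA (headers = gene IDs).
#' @param species species label; defaults to the GFF file's directory name.
#' @return a [GenomeAnnotation-class].
#' @export
readGenome <- function(gff_path, protein_fasta, cds_fasta, species = NULL) {
  if (is.null(species))
    species <- basename(dirname(normalizePath(gff_path, mustWork = FALSE)))
  gr <- tryCatch(
    rtracklayer::import(gff_path, format = "gff3"),
    error = function(e) stop("malformed GFF3 in '", gff_path, "': ",
                             conditionMessage(e), call. = FALSE))
  gr <- gr[gr$type == "gene"]
  if (!length(gr))
    stop("no 'gene' features found in ", gff_path)
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids))
    stop("every gene feature needs an ID attribute: ", gff_path)
  prot <- Biostrings::readAAStringSet(protein_fasta)
  cds <- Biostrings::readDNAStringSet(cds_fasta)
  names(prot) <- sub("\\s.*$", "", names(prot))
  names(cds) <- sub("\\s.*$", "", names(cds))
  missing <- unique(c(setdiff(ids, names(prot)), setdiff(ids, names(cds))))
  if (length(missing))
    stop("sequence missing for gene id(s): ", paste(missing, collapse = ", "))
  tab <- data.frame(
    gene_id = ids,
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  genomeAnnotation(species, tab, cds[ids], prot[ids])
}

#' Write one genome bundle to a directory
#'
#' Writes `genome.gff3`, `proteins.faa` and `cds.fna` (FASTA wrapped at 60
#' columns) for one genome, the layout [readGenome()] reads back.
#'
#' @param genome a [GenomeAnnotation-class].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
writeGenome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- geneTable(genome)
  gff <- file.path(dir, "genome.gff3")
  lines <- c("##gff-version 3",
             sprintf("%s\tRGeneAtlas\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     tab$chromosome, tab$start, tab$end, tab$strand,
                     tab$gene_id))
  writeLines(lines, gff)
  Biostrings::writeXStringSet(proteinSeqs(genome)[tab$gene_id],
                              file.path(dir, "proteins.faa"), width = 60L)
  Biostrings::writeXStringSet(cdsSeqs(genome)[tab$gene_id],
                              file.path(dir, "cds.fna"), width = 60L)
  invisible(dir)
}

#' Newick tree I/O
#'
#' Thin wrappers over [ape::write.tree()]/[ape::read.tree()]; round-trips
#' preserve topology, branch lengths and integer support labels.
#'
#' @param tree an [ape::phylo] tree.
#' @param path file path; if `NULL`, `writeNewick` returns the Newick
#'   string.
#' @return `writeNewick`: the path (or string) invisibly; `readNewick`:
#'   a `phylo`.
#' @export
writeNewick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(path))
    return(ape::write.tree(tree))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname writeNewick
#' @export
readNewick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick in '", path,
                        "' (unbalanced parentheses?)")
  tr
}

#' Read a sequence alignment from FASTA
#'
#' @param path FASTA file; gap characters (`-`) are preserved.
#' @param type `"aa"` or `"nt"`.
#' @return an `AAStringSet` or `DNAStringSet` of equal-width sequences.
#' @export
readAlignment <- function(path, type = c("nt", "aa")) {
  type <- match.arg(type)
  aln <- if (type == "aa") Biostrings::readAAStringSet(path)
         else Biostrings::readDNAStringSet(path)
  if (length(unique(Biostrings::width(aln))) > 1L)
    stop("sequences in '", path, "' are not aligned (unequal lengths)")
  aln
}

#' @rdname readAlignment
#' @param aln alignment to write.
#' @export
writeAlignment <- function(aln, path) {
  Biostrings::writeXStringSet(aln, path, width = 60L)
  invisible(path)
}

#' Tab-separated report I/O
#'
#' All pipeline stage outputs are plain TSV with a header row; an empty
#' report writes a header-only file.
#'
#' @param report a data.frame.
#' @param path output path.
#' @export
writeTable <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname writeTable
#' @export
readTable <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
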