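#' Construct a backcross genotype matrix
#'
#' In an (C57BL/6J x BALB/c)F1 x C57BL/6J backcross every offspring is, at
#' each SNP, either homozygous C57BL/6J (`B`, the F1 transmitted its B6
#' allele) or heterozygous (`H`, the F1 transmitted its BALB/c allele);
#' `N` marks a missing call.  The genotype row of a sample therefore reads
#' out the haplotype of the single F1 gamete it inherited.
#'
#' @param samples data frame with columns `sample_id` (unique) and `group`
#'   (one of [group_codes()]).
#' @param calls character matrix, `nrow(samples)` x number of markers, values
#'   in `B`/`H`/`N`; column names must be marker ids in panel order.
#' @return Object of class `genotype_matrix`: list with `samples` and
#'   `calls`.  Row names of `calls` are sample ids.
#' @export
genotype_matrix <- function(samples, calls) {
  if (!is.data.frame(samples) ||
      !all(c("sample_id", "group") %in% names(samples)))
    xo_abort("`samples` must have columns sample_id, group")
  samples <- data.frame(sample_id = as.character(samples$sample_id),
                        group = as.character(samples$group),
                        stringsAsFactors = FALSE)
  if (anyDuplicated(samples$sample_id))
    xo_abort_format("duplicate sample id")
  bad_grp <- setdiff(unique(samples$group), group_codes())
  if (length(bad_grp))
    xo_abort_format(sprintf("unknown group label: %s",
                            paste(bad_grp, collapse = ", ")))
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  if (nrow(calls) != nrow(samples))
    xo_abort(sprintf("calls has %d rows but %d samples given",
                     nrow(calls), nrow(samples)))
  if (nrow(calls) > 0) {
    ok <- matrix(calls %in% c("B", "H", "N"), nrow = nrow(calls))
    bad <- which(!ok, arr.ind = TRUE)
    if (nrow(bad))
      xo_abort_format(sprintf(
        "invalid call code '%s' at sample row %d, marker column %d",
        calls[bad[1, 1], bad[1, 2]], bad[1, 1], bad[1, 2]))
  }
  rownames(calls) <- samples$sample_id
  structure(list(samples = samples, calls = calls), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  grp <- table(factor(x$samples$group, levels = group_codes()))
  cat(sprintf("<genotype_matrix> %d samples x %d markers (%s); %.2f%% missing\n",
              nrow(x$calls), ncol(x$calls),
              paste(names(grp), grp, sep = "=", collapse = " "),
              if (length(x$calls)) 100 * mean(x$calls == "N") else 0))
  invisible(x)
}

#' Read a genotype matrix aligned to a panel
#'
#' @param path TSV (or CSV, by `sep`) with header
#'   `sample_id`, `group`, then one column per marker in panel order.
#' @param panel the [marker_panel()] the calls are aligned to.
#' @param sep field separator, default tab.
#' @return A validated [genotype_matrix()].
#' @export
read_genotypes <- function(path, panel, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, colClasses = "character",
                           check.names = FALSE)
  if (ncol(tab) != 2L + nrow(panel$markers))
    xo_abort_format(sprintf(
      "%s: %d call columns found, panel has %d markers",
      path, ncol(tab) - 2L, nrow(panel$markers)))
  if (!identical(names(tab)[1:2], c("sample_id", "group")))
    xo_abort_format(sprintf("%s: first columns must be sample_id, group", path))
  got <- names(tab)[-(1:2)]
  if (!identical(got, panel$markers$marker_id))
    xo_abort_format(sprintf("%s: marker columns do not match panel order (first mismatch: %s)",
                            path, got[got != panel$markers$marker_id][1]))
  calls <- as.matrix(tab[, -(1:2), drop = FALSE])
  genotype_matrix(tab[, 1:2], calls)
}

#' Write a genotype matrix
#'
#' Emits the dialect accepted by [read_genotypes()].
#'
#' @inheritParams read_genotypes
#' @param gm a [genotype_matrix()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, sep = "\t") {
  out <- cbind(gm$samples, as.data.frame(gm$calls, stringsAsFactors = FALSE,
                                         check.names = FALSE))
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
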