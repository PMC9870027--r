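#' @keywords internal
"_PACKAGE"

# Package-level logging: plain messages gated by a verbosity option so that
# pipeline runs can record gene counts, dropped rows etc. without cluttering
# test output.
gidee_log <- function(..., verbose = getOption("gidee.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[gidee] ", ...)
  invisible(NULL)
}

#' Strip the Ensembl version suffix from gene identifiers
#'
#' GTEx expression files and MetaXcan prediction models version Ensembl gene
#' ids inconsistently (e.g. `ENSG00000141510.16` vs `ENSG00000141510`), so all
#' cross-file gene matching in this package is done on the unversioned id:
#' everything after the first `.` is removed.
#'
#' @param ids character vector of gene identifiers.
#' @return character vector of the same length with version suffixes removed.
#' @examples
#' strip_gene_version(c("ENSG00000141510.16", "ENSG00000141510"))
#' @export
strip_gene_version <- function(ids) {
  sub("\\..*$", "", as.character(ids))
}

# Smallest positive double used to floor p-values before log transforms.
.p_floor <- .Machine$double.xmin

# stop() with a class so callers/tests can distinguish failure modes.
gidee_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "gidee_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
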