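#' Joint site frequency spectrum container
#'
#' A multidimensional array of SNP counts indexed by the combination of
#' derived-allele counts across sampled populations: one axis per population,
#' of size (haploid sample size + 1). The all-ancestral corner cell (and the
#' all-derived corner) is recorded but excluded from summary vectors, because
#' fixed cells are dominated by polarization error on real data and carry no
#' model contrast.
#'
#' @param counts numeric array with one axis per population.
#' @param pops character vector of population codes, one per axis.
#' @return an object of class `joint_sfs`.
#' @export
joint_sfs <- function(counts, pops) {
  if (length(dim(counts)) != length(pops)) {
    if (length(pops) == 1 && is.null(dim(counts))) {
      counts <- array(counts, dim = length(counts))
    } else stop("counts must have one axis per population")
  }
  if (any(counts < 0)) stop("SFS cells must be nonnegative")
  dimnames(counts) <- lapply(dim(counts), function(k) as.character(seq_len(k) - 1))
  structure(list(counts = counts, pops = pops,
                 n_hap = dim(counts) - 1L),
            class = "joint_sfs")
}

#' @export
print.joint_sfs <- function(x, ...) {
  cat("Joint SFS over", length(x$pops), "population(s):",
      paste0(x$pops, "(n=", x$n_hap, ")", collapse = " "), "\n")
  cat("Included (segregating) sites:", format(sfs_total(x)), "\n")
  invisible(x)
}

corner_cells <- function(sfs) {
  nc <- length(sfs$counts)
  c(1L, nc)  # all-ancestral and all-derived corners in R array order
}

#' Total count over included (non-corner) cells
#' @param sfs a `joint_sfs`.
#' @return scalar count of polarized segregating sites.
#' @export
sfs_total <- function(sfs) {
  sum(sfs$counts) - sum(sfs$counts[corner_cells(sfs)])
}

#' Flatten a joint SFS into the summary vector fed to the network
#'
#' @param sfs a `joint_sfs`.
#' @param drop_corners exclude the all-ancestral and all-derived corner cells
#'   (the default policy).
#' @return numeric vector in R array order (first population axis fastest).
#' @export
sfs_vector <- function(sfs, drop_corners = TRUE) {
  v <- as.vector(sfs$counts)
  if (drop_corners) v <- v[-corner_cells(sfs)]
  v
}

#' Marginalize a joint SFS onto a population subset
#'
#' Sums over the dropped axes; the included-cell total is conserved up to
#' counts that become corner cells of the marginal spectrum.
#'
#' @param sfs a `joint_sfs`.
#' @param pops nonempty subset of `sfs$pops`, in any order; the result keeps
#'   the original axis order.
#' @return a `joint_sfs` over `pops`.
#' @export
marginalize_sfs <- function(sfs, pops) {
  if (!length(pops)) stop("population subset must be nonempty")
  unknown <- setdiff(pops, sfs$pops)
  if (length(unknown)) stop("unknown population(s): ", paste(unknown, collapse = ", "))
  keep <- which(sfs$pops %in% pops)
  if (length(keep) == length(sfs$pops)) return(sfs)
  m <- apply(sfs$counts, keep, sum)
  if (length(keep) == 1) m <- array(m, dim = length(m))
  joint_sfs(m, sfs$pops[keep])
}

#' Write / read a joint SFS as tab-separated text
#'
#' The format mirrors multi-population SFS conventions: a header line naming
#' the populations, one naming the axis sizes, then the flattened counts
#' (first population axis fastest). The round trip is bit-exact.
#'
#' @param sfs a `joint_sfs`.
#' @param path file path.
#' @return `write_sfs` returns `path` invisibly; `read_sfs` a `joint_sfs`.
#' @export
write_sfs <- function(sfs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# populations:\t", paste(sfs$pops, collapse = "\t")), con)
  writeLines(paste0("# axes:\t", paste(dim(sfs$counts), collapse = "\t")), con)
  writeLines(paste(sprintf("%.17g", as.vector(sfs$counts)), collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  lines <- readLines(path)
  pops <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
  axes <- as.integer(strsplit(lines[2], "\t", fixed = TRUE)[[1]][-1])
  vals <- as.numeric(strsplit(lines[3], "\t", fixed = TRUE)[[1]])
  joint_sfs(array(vals, dim = axes), pops)
}
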