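#' LD blocks by single-linkage clustering of map positions
#'
#' Partitions the markers of each chromosome into linkage-disequilibrium
#' blocks by single-linkage agglomerative clustering of their 1-D cM
#' positions, cut so that clusters closer than `min_gap` are merged and a
#' gap of `min_gap` or more separates independent groups.  In one dimension
#' this is exactly the partition into maximal runs of adjacent markers whose
#' consecutive gaps are all smaller than `min_gap`, which is how it is
#' computed.  Clustering never crosses chromosomes.
#'
#' Markers at identical positions always share a block; ties in position are
#' ordered by marker id for reproducibility.
#'
#' @param map genetic map (see [as_genetic_map()]).
#' @param min_gap merge distance in cM (default 1.5): gaps `< min_gap`
#'   merge, gaps `>= min_gap` split.
#' @return block partition: data frame with columns `marker`, `chrom`,
#'   `block_id` (consecutive integers, chromosome by chromosome).
#' @export
single_linkage_blocks <- function(map, min_gap = 1.5) {
  map <- as_genetic_map(map)
  if (!nrow(map)) fail("empty map")
  out <- vector("list", length(unique(map$chrom)))
  nxt <- 0L
  for (k in seq_along(ch <- unique(map$chrom))) {
    i <- which(map$chrom == ch[k])
    o <- i[order(map$pos_cM[i], map$marker[i])]
    gaps <- diff(map$pos_cM[o])
    id <- nxt + cumsum(c(1L, as.integer(gaps >= min_gap)))
    nxt <- max(id)
    out[[k]] <- data.frame(marker = map$marker[o], chrom = ch[k],
                           block_id = id)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' LD blocks from recombination bins
#'
#' One block per (chromosome, bin) pair, for maps whose markers carry
#' recombination-bin labels (the independence unit used for dense GBS maps,
#' where map positions within a bin are not resolved).
#'
#' @param map genetic map with a complete `bin` column.
#' @return block partition as in [single_linkage_blocks()]; blocks are
#'   ordered by chromosome (input order) then bin.
#' @export
bins_as_blocks <- function(map) {
  map <- as_genetic_map(map)
  if (anyNA(map$bin)) fail("bins_as_blocks needs a bin label for every marker")
  key <- paste(map$chrom, map$bin, sep = "\r")
  lev <- unique(key[order(match(map$chrom, unique(map$chrom)), map$bin)])
  res <- data.frame(marker = map$marker, chrom = map$chrom,
                    block_id = match(key, lev))
  res[order(res$block_id, res$marker), , drop = FALSE] -> res
  rownames(res) <- NULL
  res
}

## number of blocks in a partition
n_blocks <- function(blocks) length(unique(blocks$block_id))
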