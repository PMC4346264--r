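# Library chemistry constants and bundled reference sequences.
#
# The 3' DNA adapter and the six barcoded 5' RNA adapters are the published
# library design for six multiplexed small-RNA libraries per sequencing run.
# Sequencing starts inside the 5' adapter: the forward PCR primer covers its
# first 21 nt, so every read begins with a constant 9-nt remnant, the last
# 5 nt of the shared adapter body (CGAUC) followed by the 4-nt barcode.

#' The ten small-RNA annotation categories
#'
#' Fixed category vocabulary used by the reference set and the annotation
#' stage: mRNA, rRNA, scRNA, snRNA, srpRNA, miRNA, lncRNA, piRNA, snoRNA,
#' tRNA.
#'
#' @format Character vector of length 10.
#' @export
rna_categories <- c("mRNA", "rRNA", "scRNA", "snRNA", "srpRNA",
                    "miRNA", "lncRNA", "piRNA", "snoRNA", "tRNA")

#' The 31-nt Y4-RNA 5' fragment
#'
#' The dominant 31-nt plasma species, the 5'-terminal fragment of 94-nt
#' Y4-RNA. It can fold into a 5'-half-tRNA-like structure and act as a
#' tRNase Z(L) small guide RNA.
#'
#' @format RNA string (character scalar).
#' @seealso [rna_y_target], [fold_half_trna()], [find_target_sites()]
#' @export
y4_fragment_31nt <- "GGCUGGUCCGAUGGUAGUGGGUUAUCAGAAC"

#' The 46-nt model target RNA-Y
#'
#' A model target RNA designed to form a pre-tRNA-like complex with
#' [y4_fragment_31nt]: it supplies a T-arm-like stem-loop, the acceptor-stem
#' 3' strand complementary to the guide's 5' arm, the discriminator
#' nucleotide, and a 3' trailer that is released by guided cleavage.
#'
#' @format RNA string (character scalar).
#' @export
rna_y_target <- "GGAGUUCUAGAUUCCAGGUUCGACUCCUGGACCAGCCGGUGUAAGC"

# 14-nt rRNA-derived fragments used in the bundled reference surrogate.
rrna_28s_fragment_14nt <- "CGCGACCUCAGAUC"
rrna_58s_fragment_14nt <- "GUCUGAGCGUCGCU"

# Shared 26-nt body of the six 5' RNA adapters (without barcode).
.adapter5_body <- "GUUCAGAGUUCUACAGUCCGACGAUC"

#' Default adapter and barcode configuration
#'
#' Returns the library-chemistry configuration used throughout
#' preprocessing: the 25-nt 3' adapter (RNA alphabet), the six barcoded
#' 30-nt 5' adapters, the constant 9-nt 5' remnant layout of each read
#' (5 fixed nt + 4-nt barcode), and the matching tolerances.
#'
#' @param seed_len Length of the 3'-adapter prefix used as the trimming
#'   seed (default 8).
#' @param seed_mismatch Maximum mismatches tolerated in the trimming seed
#'   (default 1).
#' @param max_bc_mismatch Maximum mismatches tolerated when matching the
#'   read barcode against the barcode table (default 0).
#' @param artifact_min_match Minimum number of matching positions for a
#'   local 5'-adapter match to flag an insert as an adapter artifact
#'   (default 10).
#' @param artifact_mismatch Maximum mismatches tolerated inside such a
#'   local match (default 1).
#'
#' @return A list with elements `adapter3`, `adapters5` (named by barcode),
#'   `barcodes`, `remnant`, `remnant_len`, `barcode_start`, `barcode_len`,
#'   and the tolerance parameters.
#' @examples
#' cfg <- adapter_config()
#' cfg$adapter3
#' cfg$barcodes
#' @export
adapter_config <- function(seed_len = 8L, seed_mismatch = 1L,
                           max_bc_mismatch = 0L,
                           artifact_min_match = 10L, artifact_mismatch = 1L) {
  barcodes <- c("GAAA", "AAAA", "AGAA", "ACAA", "CAAA", "UAAA")
  adapters5 <- paste0(.adapter5_body, barcodes)
  names(adapters5) <- barcodes
  remnant_fixed <- substr(.adapter5_body, 22L, 26L)  # "CGAUC"
  list(
    adapter3 = "AUCUCGUAUGCCGUCUUCUGCUUGU",
    adapters5 = adapters5,
    barcodes = barcodes,
    remnant = remnant_fixed,
    remnant_len = nchar(remnant_fixed) + 4L,  # fixed part + barcode
    barcode_start = nchar(remnant_fixed) + 1L,
    barcode_len = 4L,
    seed_len = as.integer(seed_len),
    seed_mismatch = as.integer(seed_mismatch),
    max_bc_mismatch = as.integer(max_bc_mismatch),
    artifact_min_match = as.integer(artifact_min_match),
    artifact_mismatch = as.integer(artifact_mismatch)
  )
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
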