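#' Construct a domain map
#'
#' @param intervals data.frame/`DataFrame` with columns `name`, `start`,
#'   `end`, `tier` (`"lobe"`, `"domain"` or `"subdomain"`); 1-based
#'   inclusive residue coordinates.
#' @param proteinLength Total protein length in residues (2,286 for human
#'   POLE).
#' @return A validated [DomainMap-class].
#' @seealso [defaultDomainMap()], [annotateDomains()]
#' @export
DomainMap <- function(intervals, proteinLength = 2286L) {
  iv <- S4Vectors::DataFrame(intervals)
  iv$start <- as.integer(iv$start)
  iv$end <- as.integer(iv$end)
  iv$name <- as.character(iv$name)
  iv$tier <- as.character(iv$tier)
  new("DomainMap", proteinLength = as.integer(proteinLength), intervals = iv)
}

#' Read a domain map from JSON
#'
#' Expects `{"protein_length": n, "intervals": [{"name": ..., "start": ...,
#' "end": ..., "tier": ...}, ...]}`.
#'
#' @param path Path to a JSON file.
#' @return A [DomainMap-class].
#' @export
readDomainMap <- function(path) {
  j <- jsonlite::fromJSON(path)
  DomainMap(j$intervals, j$protein_length)
}

#' The package's default POLE domain map
#'
#' The N-terminal lobe (NTL) spans residues 1--1,183 and contains the
#' exonuclease (proofreading) domain, here 268--471 -- the
#' literature-standard interval containing all 20 catalogued driver residues
#' (275--465) -- and the polymerase domain with palm, fingers and thumb
#' subdomains.  The C-terminal lobe (CTL) spans 1,184--2,286 and contains the
#' CTD.  Subdomain and non-ExoD domain boundaries are package defaults and
#' can be overridden by supplying a custom map.
#'
#' @return A [DomainMap-class] over 2,286 residues.
#' @examples
#' defaultDomainMap()
#' @export
defaultDomainMap <- function() {
  readDomainMap(system.file("extdata", "pole_domain_map.json",
                            package = "poleSig", mustWork = TRUE))
}

#' Annotate parsed variants with domain and lobe
#'
#' Each variant with a resolvable residue position (multi-residue events use
#' their start residue) is assigned the innermost matching interval
#' (`domain`) and its lobe (`NTL`/`CTL`).  Lobe assignment is total: every
#' residue from 1 to the protein length belongs to exactly one lobe.
#' Splice records without a residue position are left `NA`.
#'
#' @param variants `DataFrame` from [parsePoleVariants()].
#' @param map A [DomainMap-class]; defaults to [defaultDomainMap()].
#' @return `variants` with `domain` and `lobe` columns added.
#' @examples
#' v <- parsePoleVariants(c("P286R", "R680C", "E1376D"))
#' annotateDomains(v)$domain
#' @export
annotateDomains <- function(variants, map = defaultDomainMap()) {
  pos <- variants$position
  known <- !is.na(pos)
  if (any(pos[known] > proteinLength(map)))
    stop("residue position beyond protein length (",
         proteinLength(map), "): ",
         paste(pos[known][pos[known] > proteinLength(map)], collapse = ", "))
  iv <- as.data.frame(map@intervals)
  lookup <- function(p, tiers) {
    hit <- iv[iv$tier %in% tiers & iv$start <= p & iv$end >= p, ,
              drop = FALSE]
    if (!nrow(hit)) return(NA_character_)
    # innermost = narrowest interval across the requested tiers
    hit$name[which.min(hit$end - hit$start)]
  }
  variants$lobe <- ifelse(known,
    vapply(pos, function(p)
      if (is.na(p)) NA_character_ else lookup(p, "lobe"), ""),
    NA_character_)
  variants$domain <- ifelse(known,
    vapply(pos, function(p) {
      if (is.na(p)) return(NA_character_)
      d <- lookup(p, c("domain", "subdomain"))
      if (is.na(d)) lookup(p, "lobe") else d
    }, ""),
    NA_character_)
  variants
}
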