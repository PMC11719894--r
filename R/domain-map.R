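#' Seven-domain ORF2p residue map
#'
#' Default residue intervals for the seven ORF2p domains: EN 1-238,
#' tower 239-439, fingers 440-557, palm 558-775, thumb 776-862,
#' wrist 863-1061, CTD 1061-1275. Residue 1061 is shared by wrist and CTD
#' exactly as annotated; overlapping membership is allowed and per-domain
#' selections include shared residues in both domains.
#'
#' With `adjusted = TRUE` the CTD and wrist intervals become 1068-1275 and
#' 877-1056. This trimmed preset is meant for CTD-wrist minimum-distance
#' analyses, where the chain-adjacent wrist/CTD termini would otherwise
#' contribute trivial contacts present in every frame.
#'
#' @param adjusted use the trimmed CTD/wrist intervals for interdomain
#'   contact analysis.
#' @return A [DomainMap-class].
#' @examples
#' orf2pDomainMap()
#' domainRange(orf2pDomainMap(adjusted = TRUE), "CTD")
#' @export
orf2pDomainMap <- function(adjusted = FALSE) {
  iv <- list(EN = c(1, 238), tower = c(239, 439), fingers = c(440, 557),
             palm = c(558, 775), thumb = c(776, 862), wrist = c(863, 1061),
             CTD = c(1061, 1275))
  if (adjusted) {
    iv$wrist <- c(877, 1056)
    iv$CTD <- c(1068, 1275)
  }
  DomainMap(iv)
}

#' Read a domain map from a YAML config
#'
#' The file maps each domain name to a two-element `[start, end]` residue
#' interval (1-based, inclusive), e.g. `EN: [1, 238]`.
#'
#' @param path YAML file path.
#' @return A [DomainMap-class].
#' @export
readDomainMap <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- yaml::read_yaml(path)
  if (!length(raw)) stop("domain map file defines no domains")
  bad <- names(raw)[vapply(raw, length, integer(1)) != 2L]
  if (length(bad))
    stop("domain(s) must be [start, end] pairs: ", paste(bad, collapse = ", "))
  DomainMap(lapply(raw, as.integer))
}

#' Write a domain map to YAML
#'
#' @param map a [DomainMap-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeDomainMap <- function(map, path) {
  iv <- lapply(domainNames(map), function(n) as.integer(domainRange(map, n)))
  names(iv) <- domainNames(map)
  yaml::write_yaml(iv, path)
  invisible(path)
}
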