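#' Construct a directed signaling network
#'
#' A network model is the topology over which all signaling is defined:
#' named regions, directed region-to-region edges along which signaling is
#' possible, and latent inputs -- unobserved external drives entering the
#' network at designated regions.
#'
#' Edges are stored in a deterministic order (by source region, then target,
#' in declared region order) so that parameter vectors indexed by connection
#' have a stable layout across runs. Self-loops are disallowed: the
#' fixed-point solve of the signaling model assumes a hollow weighting
#' diagonal.
#'
#' @param regions Character vector of unique region names.
#' @param edges Data frame with columns `from`, `to` (region names), or a
#'   list of 2-element character vectors.
#' @param latents Data frame with columns `name`, `target`, or a list of
#'   2-element character vectors (`name`, `target`). May be empty.
#' @param name Free-text label for the network.
#'
#' @return An object of class `bold_network`: a list with elements
#'   `name`, `regions`, `edges` (tibble `from`, `to`), `latents` (tibble
#'   `name`, `target`).
#' @export
#' @examples
#' net <- network_model(
#'   regions = c("A", "B"),
#'   edges = data.frame(from = "A", to = "B"),
#'   latents = data.frame(name = "L0", target = "A")
#' )
#' n_connections(net)
network_model <- function(regions, edges = NULL, latents = NULL,
                          name = "network") {
  regions <- as.character(regions)
  edges <- as_edge_tibble(edges, c("from", "to"))
  latents <- as_edge_tibble(latents, c("name", "target"))

  # canonical deterministic ordering: declared region order
  if (nrow(edges)) {
    ord <- order(match(edges$from, regions), match(edges$to, regions))
    edges <- edges[ord, , drop = FALSE]
  }
  net <- structure(
    list(name = name, regions = regions, edges = edges, latents = latents),
    class = "bold_network"
  )
  report <- validate_network(net)
  fails <- report$check[!report$pass]
  abort_if(length(fails) > 0,
           paste0("invalid network model:\n  - ",
                  paste(report$detail[!report$pass], collapse = "\n  - ")))
  net
}

as_edge_tibble <- function(x, nms) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0) || length(x) == 0) {
    out <- tibble::tibble(a = character(), b = character())
    names(out) <- nms
    return(out)
  }
  if (is.data.frame(x)) {
    abort_if(!all(nms %in% names(x)),
             paste0("edge table must have columns ", paste(nms, collapse = ", ")))
    return(tibble::as_tibble(x[, nms]))
  }
  if (is.list(x)) {
    abort_if(!all(vapply(x, length, 1L) == 2L),
             "edge list entries must have exactly 2 elements")
    out <- tibble::tibble(
      a = vapply(x, function(e) as.character(e[[1]]), ""),
      b = vapply(x, function(e) as.character(e[[2]]), "")
    )
    names(out) <- nms
    return(out)
  }
  stop("cannot interpret edges/latents input", call. = FALSE)
}

#' Validate a network model
#'
#' Runs every structural invariant the signaling model relies on and reports
#' each check with a pass/fail flag. The network is usable by the fitting
#' engine iff the failure list is empty. This never throws: it is a
#' diagnostics-reporting operation.
#'
#' @param net A `bold_network` (or a bare list with the same fields).
#' @return A tibble with columns `check`, `pass`, `detail`; one row per
#'   violation or per passed invariant class.
#' @export
validate_network <- function(net) {
  regions <- as.character(net$regions)
  edges <- net$edges
  latents <- net$latents
  rows <- list()
  add <- function(check, pass, detail) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      check = check, pass = pass, detail = detail
    )
  }

  dup_r <- unique(regions[duplicated(regions)])
  if (length(dup_r)) {
    add("unique_regions", FALSE,
        paste0("duplicated region name(s): ", paste(dup_r, collapse = ", ")))
  } else {
    add("unique_regions", TRUE, "region names unique")
  }

  bad_ep <- unique(c(setdiff(edges$from, regions), setdiff(edges$to, regions)))
  if (length(bad_ep)) {
    add("edge_endpoints_declared", FALSE,
        paste0("edge endpoint(s) not declared as regions: ",
               paste(bad_ep, collapse = ", ")))
  } else {
    add("edge_endpoints_declared", TRUE, "all edge endpoints declared")
  }

  bad_lt <- unique(setdiff(latents$target, regions))
  if (length(bad_lt)) {
    add("latent_targets_declared", FALSE,
        paste0("latent target(s) not declared as regions: ",
               paste(bad_lt, collapse = ", ")))
  } else {
    add("latent_targets_declared", TRUE, "all latent targets declared")
  }

  key <- paste(edges$from, edges$to, sep = "->")
  dup_e <- unique(key[duplicated(key)])
  if (length(dup_e)) {
    add("no_duplicate_edges", FALSE,
        paste0("duplicated edge(s): ", paste(dup_e, collapse = ", ")))
  } else {
    add("no_duplicate_edges", TRUE, "no duplicate edges")
  }

  loops <- unique(edges$from[edges$from == edges$to])
  if (length(loops)) {
    add("no_self_loops", FALSE,
        paste0("self-loop edge(s) at: ", paste(loops, collapse = ", ")))
  } else {
    add("no_self_loops", TRUE, "no self-loops")
  }

  has_input <- regions %in% c(edges$to, latents$target)
  if (any(!has_input)) {
    add("every_region_has_input", FALSE,
        paste0("region(s) with no incoming edge or latent input: ",
               paste(regions[!has_input], collapse = ", ")))
  } else {
    add("every_region_has_input", TRUE, "every region receives input")
  }

  dup_ln <- unique(latents$name[duplicated(latents$name)])
  if (length(dup_ln)) {
    add("unique_latent_names", FALSE,
        paste0("duplicated latent name(s): ", paste(dup_ln, collapse = ", ")))
  } else {
    add("unique_latent_names", TRUE, "latent names unique")
  }

  dplyr::bind_rows(rows)
}

#' @export
print.bold_network <- function(x, ...) {
  cat(sprintf("<bold_network> %s: %d regions, %d edges, %d latent input(s)\n",
              x$name, length(x$regions), nrow(x$edges), nrow(x$latents)))
  invisible(x)
}

#' Number of connections in a network
#'
#' Counts region-to-region edges plus latent-input edges; this is the family
#' size used for family-wise error correction.
#'
#' @param net A `bold_network`.
#' @param include_latents Count latent-input edges as connections?
#' @return Integer count.
#' @export
n_connections <- function(net, include_latents = TRUE) {
  nrow(net$edges) + if (include_latents) nrow(net$latents) else 0L
}

#' Stable connection labels
#'
#' `"from->to"` labels for every connection: region-to-region edges first
#' (canonical order), then latent-input edges. Parameter vectors (D, B,
#' DB) are indexed by these labels throughout.
#'
#' @param net A `bold_network`.
#' @return Character vector.
#' @export
connection_labels <- function(net) {
  c(paste(net$edges$from, net$edges$to, sep = "->"),
    if (nrow(net$latents)) paste(net$latents$name, net$latents$target, sep = "->"))
}

#' Load / save a network model (JSON)
#'
#' The interchange format is JSON with keys `name`, `regions` (array),
#' `edges` (array of 2-element arrays `[from, to]`) and `latents` (array of
#' objects `{name, target}`). `save_network()` followed by `load_network()`
#' round-trips to an identical model.
#'
#' @param path File path of the network spec.
#' @return `load_network()` returns a validated `bold_network`.
#' @export
load_network <- function(path) {
  abort_if(!file.exists(path), paste0("network spec not found: ", path))
  spec <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop("network spec parse error: ", conditionMessage(e),
                             call. = FALSE)
  )
  for (field in c("name", "regions")) {
    abort_if(is.null(spec[[field]]),
             paste0("network spec parse error: missing field '", field, "'"))
  }
  edges <- lapply(spec$edges %||% list(), function(e) {
    abort_if(length(e) != 2,
             "network spec parse error: field 'edges' entries must be 2-element lists")
    c(e[[1]], e[[2]])
  })
  latents <- lapply(spec$latents %||% list(), function(l) {
    abort_if(is.null(l$name) || is.null(l$target),
             "network spec parse error: field 'latents' entries need {name, target}")
    c(l$name, l$target)
  })
  network_model(regions = unlist(spec$regions), edges = edges,
                latents = latents, name = spec$name)
}

#' @param net A `bold_network` to serialize.
#' @rdname load_network
#' @export
save_network <- function(net, path) {
  spec <- list(
    name = net$name,
    regions = as.list(net$regions),
    edges = purrr::map2(net$edges$from, net$edges$to, ~ list(.x, .y)),
    latents = purrr::map2(net$latents$name, net$latents$target,
                          ~ list(name = .x, target = .y))
  )
  jsonlite::write_json(spec, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Bundled network fixtures
#'
#' `brain_network()` is the 14-region brain nociceptive/pain network:
#' anterior cingulate (AC), posterior cingulate (PC), insular cortex (IC),
#' Heschl's gyrus (HG), frontal orbital cortex (FOrb), hippocampus (Hippo),
#' hypothalamus (Hypo), amygdala (Amyg), thalamus (Thal), nucleus accumbens
#' (NAcc), ventral tegmental area (VTA), periaqueductal gray (PAG),
#' parabrachial nuclei (PBN) and locus coeruleus (LC), with three latent
#' inputs: Lat0 to FOrb, Lat1 to IC, Lat2 to LC. The edge set comprises the
#' connections named in published group-connectivity tables for this network
#' plus two canonical-anatomy edges (VTA to NAcc, Hypo to VTA) supplied so
#' that every region receives input, as the model requires.
#'
#' `brainstem_cord_network()` is the 10-region brainstem/spinal-cord
#' network: Thal, Hypo, PAG, LC, PBN, nucleus tractus solitarius (NTS),
#' nucleus gigantocellularis (NGc), nucleus raphe magnus (NRM), dorsal
#' reticular nucleus (DRt) and the C6 right dorsal horn (C6RD). Edges not
#' named in the connectivity tables follow standard descending
#' pain-modulation anatomy (PAG to NRM/NGc, medullary projections to C6RD,
#' reciprocal cord-to-brainstem feedback).
#'
#' @param source One of `"builtin"` (construct in code) or a file path to a
#'   JSON spec to load instead.
#' @return A validated `bold_network`.
#' @export
brain_network <- function(source = "builtin") {
  if (!identical(source, "builtin")) return(load_network(source))
  network_model(
    name = "brain",
    regions = c("AC", "PC", "IC", "HG", "FOrb", "Hippo", "Hypo", "Amyg",
                "Thal", "NAcc", "VTA", "PAG", "PBN", "LC"),
    edges = list(
      c("AC", "PC"), c("AC", "IC"), c("AC", "FOrb"), c("AC", "Amyg"),
      c("PC", "AC"),
      c("IC", "AC"), c("IC", "HG"),
      c("Hypo", "PAG"), c("Hypo", "Thal"), c("Hypo", "VTA"),
      c("Amyg", "Thal"), c("Amyg", "Hippo"),
      c("Thal", "AC"), c("Thal", "PC"), c("Thal", "Hypo"), c("Thal", "Hippo"),
      c("VTA", "NAcc"),
      c("PBN", "Thal"),
      c("LC", "PBN"), c("LC", "Thal")
    ),
    latents = list(c("Lat0", "FOrb"), c("Lat1", "IC"), c("Lat2", "LC"))
  )
}

#' @rdname brain_network
#' @export
brainstem_cord_network <- function(source = "builtin") {
  if (!identical(source, "builtin")) return(load_network(source))
  network_model(
    name = "brainstem_cord",
    regions = c("Thal", "Hypo", "PAG", "LC", "PBN", "NTS", "NGc", "NRM",
                "DRt", "C6RD"),
    edges = list(
      c("Thal", "Hypo"),
      c("Hypo", "PAG"), c("Hypo", "NTS"), c("Hypo", "Thal"),
      c("PAG", "NRM"), c("PAG", "NGc"),
      c("LC", "Thal"), c("LC", "PBN"),
      c("PBN", "Thal"),
      c("NGc", "C6RD"),
      c("NRM", "C6RD"),
      c("DRt", "C6RD"),
      c("C6RD", "DRt")
    ),
    latents = list(c("Lat2", "LC"))
  )
}

#' Region-name alias table
#'
#' Canonical short codes with the long anatomical names they stand for;
#' useful when matching figure labels against text labels.
#'
#' @return A tibble with columns `code`, `long_name`.
#' @export
region_aliases <- function() {
  tibble::tribble(
    ~code,   ~long_name,
    "AC",    "anterior cingulate cortex",
    "PC",    "posterior cingulate cortex",
    "IC",    "insular cortex",
    "HG",    "Heschl's gyrus",
    "FOrb",  "frontal orbital cortex",
    "Hippo", "hippocampus",
    "Hypo",  "hypothalamus",
    "Amyg",  "amygdala",
    "Thal",  "thalamus",
    "NAcc",  "nucleus accumbens",
    "VTA",   "ventral tegmental area",
    "PAG",   "periaqueductal gray",
    "PBN",   "parabrachial nuclei",
    "LC",    "locus coeruleus",
    "NTS",   "nucleus tractus solitarius",
    "NGc",   "nucleus gigantocellularis",
    "NRM",   "nucleus raphe magnus",
    "DRt",   "dorsal reticular nucleus of the medulla",
    "C6RD",  "right dorsal horn, 6th cervical segment"
  )
}
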