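#' Ideal alpha-helix CA trace
#'
#' CA coordinates of an idealised straight alpha helix: radius 2.3 A,
#' rise 1.5 A per residue, 100 degrees of turn per residue.
#'
#' @param n Residue count.
#' @param radius,rise,turn_deg Helix parameters.
#' @return `n x 3` CA coordinate matrix.
#' @export
ideal_helix <- function(n, radius = 2.3, rise = 1.5, turn_deg = 100) {
  k <- seq_len(n) - 1L
  th <- k * turn_deg * pi / 180
  cbind(radius * cos(th), radius * sin(th), rise * k)
}

#' Generate deterministic fixture files
#'
#' Writes small, fully reproducible inputs for pipeline smoke tests:
#' toy monomer/dimer structures (ideal helices with known geometry),
#' prediction fixtures with prescribed confidence patterns, or a
#' simulated colony screen.
#'
#' @param kind One of `"toy-monomer"`, `"toy-complex"`, `"prediction"`,
#'   `"tic-screen"`.
#' @param dir Output directory (created if needed).
#' @param seed Seed controlling any randomised content.
#' @param n Residue count for structure fixtures (default 36).
#' @return Character vector of written file paths, invisibly; the
#'   constructed objects as the `objects` attribute.
#' @export
make_fixtures <- function(kind = c("toy-monomer", "toy-complex", "prediction",
                                   "tic-screen"),
                          dir = tempdir(), seed = 1L, n = 36L) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  objects <- list()
  if (kind %in% c("toy-monomer", "toy-complex")) {
    two <- kind == "toy-complex"
    ca <- ideal_helix(n)
    if (two) {
      ca2 <- ideal_helix(n)
      ca2[, 1] <- ca2[, 1] + 9
      co <- rbind(ca, ca2)
      s <- pd_structure(co, chain_lengths = c(n, n))
      sq <- with_local_seed(seed, chained_seq(
        c(paste(sample(AA_DESIGN, n, TRUE), collapse = ""),
          paste(sample(AA_DESIGN, n, TRUE), collapse = ""))))
    } else {
      s <- pd_structure(ca)
      sq <- with_local_seed(seed, chained_seq(
        paste(sample(AA_DESIGN, n, TRUE), collapse = "")))
    }
    pdb <- file.path(dir, paste0(kind, ".pdb"))
    fa <- file.path(dir, paste0(kind, ".fasta"))
    write_structure_pdb(s, pdb, sequence = sq)
    write_chained_fasta(sq, fa, name = kind)
    files <- c(pdb, fa)
    objects <- list(structure = s, sequence = sq)
  } else if (kind == "prediction") {
    s <- pd_structure(ideal_helix(n))
    plddt <- rep(85, n)
    pae <- matrix(31.75 / 4, n, n); diag(pae) <- 0
    p <- pd_prediction(s, plddt, pae, ptm_from_pae(pae))
    pdb <- file.path(dir, "prediction.pdb")
    conf <- file.path(dir, "prediction_confidence.csv")
    write_structure_pdb(s, pdb, b = plddt)
    utils::write.csv(data.frame(residue = seq_len(n), plddt = plddt,
                                mean_pae = rowMeans(pae), ptm = p$ptm),
                     conf, row.names = FALSE)
    files <- c(pdb, conf)
    objects <- list(prediction = p)
  } else if (kind == "tic-screen") {
    screen <- simulate_screen(seed = seed)
    csv <- file.path(dir, "tic_screen.csv")
    utils::write.csv(screen, csv, row.names = FALSE)
    files <- csv
    objects <- list(screen = screen)
  }
  attr(files, "objects") <- objects
  invisible(files)
}

#' Run manifest: config, seeds and output digests
#'
#' Ties every pipeline output to the configuration and seeds that
#' produced it. Digests (MD5) are recomputed from the files on disk, so
#' a manifest can later be verified against (or used to re-run) a
#' deterministic stage.
#'
#' @param config List of configuration values.
#' @param seed The run seed.
#' @param inputs,outputs Character vectors of file paths.
#' @param stage Stage label.
#' @return Object of class `run_manifest`.
#' @export
run_manifest <- function(config, seed, outputs, inputs = character(0),
                         stage = "run") {
  digest <- function(paths) {
    if (!length(paths)) return(list())
    as.list(tools::md5sum(paths))
  }
  structure(list(stage = stage,
                 package = "protdesign",
                 version = as.character(utils::packageVersion("protdesign")),
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 seed = seed, config = config,
                 inputs = digest(inputs), outputs = digest(outputs)),
            class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest A `run_manifest` (or path to one).
#' @param path File path for reading/writing.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_manifest
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(m) <- "run_manifest"
  m
}

#' @rdname run_manifest
#' @export
verify_manifest <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  paths <- names(manifest$outputs)
  ok <- vapply(paths, function(p) {
    file.exists(p) && identical(unname(tools::md5sum(p)),
                                unname(unlist(manifest$outputs[[p]])))
  }, TRUE)
  all(ok)
}
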