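# NIfTI and delimited-text serialization. Volumes are written RAS with
# the isotropic voxel size in the header and provenance in a JSON
# sidecar; complex volumes are written as magnitude/phase pairs.

#' Write a volume (or phantom parameter grid) as NIfTI
#'
#' Complex data are split into `<path>_mag.nii` and `<path>_phase.nii`;
#' real data go to `<path>.nii`. A JSON sidecar `<path>.json` records
#' provenance.
#'
#' @param vol An `image_volume`, or a numeric/complex array.
#' @param path Output path prefix (".nii" appended as needed).
#' @param voxel_size Voxel size (mm); taken from the `image_volume` when
#'   available.
#' @return Character vector of files written, invisibly.
#' @export
write_volume_nifti <- function(vol, path, voxel_size = NULL) {
  prov <- list()
  if (inherits(vol, "image_volume")) {
    voxel_size <- voxel_size %||% vol$voxel_size
    prov <- vol$provenance
    vol <- vol$data
  }
  voxel_size <- voxel_size %||% 1
  path <- sub("\\.nii(\\.gz)?$", "", path)
  mk <- function(a, p) {
    im <- RNifti::asNifti(a)
    RNifti::pixdim(im) <- rep(voxel_size, length(dim(a)))
    RNifti::writeNifti(im, p)
    p
  }
  files <- if (is.complex(vol)) {
    c(mk(Mod(vol), paste0(path, "_mag.nii")),
      mk(Arg(vol), paste0(path, "_phase.nii")))
  } else {
    mk(vol, paste0(path, ".nii"))
  }
  side <- paste0(path, ".json")
  jsonlite::write_json(
    c(list(voxel_size_mm = voxel_size), .jsonable(prov)),
    side, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(files, side))
}

.jsonable <- function(x) {
  if (is.list(x)) return(lapply(x, .jsonable))
  if (is.null(x) || length(x) == 0) return(NULL)
  x
}

#' Read a real-valued NIfTI volume
#'
#' @param path NIfTI file path.
#' @return An `image_volume` (real data; voxel size from the header).
#' @export
read_volume_nifti <- function(path) {
  im <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(im)[1]
  image_volume(array(as.numeric(im), dim(im)), vox,
               provenance = list(source = path))
}

#' Serialize simulated k-space with its trajectory
#'
#' Writes `<prefix>_kspace.tsv` (half_projection, sample, coil, re, im),
#' `<prefix>_traj.tsv` (via [write_trajectory()]) and a JSON sidecar
#' with noise_sd and seed.
#'
#' @param kspace A [kspace_data()] object.
#' @param prefix Output path prefix.
#' @return Character vector of files written, invisibly.
#' @export
write_kspace <- function(kspace, prefix) {
  traj <- kspace$traj
  ktab <- data.frame(
    half_projection = rep(rep(seq_len(traj$n_half), each = traj$n_samp),
                          kspace$n_coils),
    sample = rep(rep(seq_len(traj$n_samp), traj$n_half), kspace$n_coils),
    coil = rep(seq_len(kspace$n_coils),
               each = traj$n_half * traj$n_samp),
    re = as.vector(Re(kspace$samples)),
    im = as.vector(Im(kspace$samples)))
  kf <- paste0(prefix, "_kspace.tsv")
  utils::write.table(ktab, kf, sep = "\t", row.names = FALSE, quote = FALSE)
  tf <- write_trajectory(traj, paste0(prefix, "_traj.tsv"))
  sf <- paste0(prefix, "_meta.json")
  jsonlite::write_json(
    c(list(noise_sd = kspace$noise_sd, seed = kspace$seed,
           n_coils = kspace$n_coils, kmax = traj$kmax),
      .jsonable(kspace$meta)),
    sf, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(kf, tf, sf))
}

#' @rdname write_kspace
#' @param prefix Path prefix used when writing.
#' @export
read_kspace <- function(prefix) {
  traj <- read_trajectory(paste0(prefix, "_traj.tsv"))
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  ktab <- utils::read.table(paste0(prefix, "_kspace.tsv"), header = TRUE,
                            sep = "\t")
  ktab <- ktab[order(ktab$coil, ktab$half_projection, ktab$sample), ]
  samples <- matrix(complex(real = ktab$re, imaginary = ktab$im),
                    traj$n_half * traj$n_samp, meta$n_coils)
  traj$kmax <- meta$kmax
  kspace_data(samples, traj, noise_sd = meta$noise_sd,
              seed = meta$seed,
              meta = meta[setdiff(names(meta),
                                  c("noise_sd", "seed", "n_coils", "kmax"))])
}
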