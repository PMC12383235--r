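# Independent residue-mass oracle: IUPAC average residue masses
# (residue = amino acid minus water); peptide mass = sum + one water.
RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

peptide_average_mass <- function(seq) {
  aa <- strsplit(seq, "")[[1]]
  sum(RESIDUE_MASS[aa]) + 18.0153
}

# straight horizontal tube rendered in a small field
render_straight_tube <- function(length_nm = 48, diameter = 2.8,
                                 voxel = 0.5, blur_sd = 0, noise_sd = 0,
                                 seed = 1, mode = "slice") {
  margin <- 2 * diameter + 2
  ext <- length_nm + 2 * margin
  y <- ext / 2
  cl <- cbind(seq(margin, margin + length_nm, by = 0.5), rep(y, 0))
  cl <- cbind(seq(margin, margin + length_nm, by = 0.5),
              rep(y, length(seq(margin, margin + length_nm, by = 0.5))))
  tr <- assembly_truth("curvilinear", centerline = cl, tube_diameter = diameter)
  gen_density_field(list(tr), dims = round(c(ext, ext) / voxel),
                    voxel_size = voxel, blur_sd = blur_sd,
                    noise_sd = noise_sd, seed = seed, mode = mode)
}

# hand-built cross profile from an analytic function of offset
make_profile <- function(fun, half_width = 10, spacing = 0.002,
                         baseline = 0, threshold_fraction = 0.15) {
  offs <- seq(-half_width, half_width, by = spacing)
  structure(list(offsets = offs, values = fun(offs), baseline = baseline,
                 noise_sd = 0, threshold_fraction = threshold_fraction,
                 spacing = spacing),
            class = "cross_profile")
}
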