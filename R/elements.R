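#' Monoisotopic element masses
#'
#' Masses (Da) of the most abundant isotope of each element, from the NIST
#' atomic weights and isotopic compositions compilation. Used by
#' [calculate_mass()] and, together with the electron mass, to derive the
#' packaged adduct definitions.
#'
#' @return Named numeric vector of monoisotopic masses in Da.
#' @examples
#' element_masses()[c("C", "H", "O")]
#' @export
element_masses <- function() .element_masses

.element_masses <- c(
    H  = 1.0078250319, He = 4.0026032542, Li = 7.0160034366, Be = 9.0121830650,
    B  = 11.0093053645, C = 12.0, N = 14.0030740052, O = 15.9949146221,
    F  = 18.9984031627, Ne = 19.9924401762, Na = 22.9897692820,
    Mg = 23.9850417000, Al = 26.9815385300, Si = 27.9769265347,
    P  = 30.9737619984, S = 31.9720711744, Cl = 34.9688526820,
    Ar = 39.9623831237, K = 38.9637064864, Ca = 39.9625908630,
    Sc = 44.9559082800, Ti = 47.9479419800, V = 50.9439570400,
    Cr = 51.9405062300, Mn = 54.9380439100, Fe = 55.9349363300,
    Co = 58.9331942900, Ni = 57.9353424100, Cu = 62.9295977200,
    Zn = 63.9291420100, Ga = 68.9255735000, Ge = 73.9211777610,
    As = 74.9215945700, Se = 79.9165218000, Br = 78.9183376000,
    Kr = 83.9114977282, Rb = 84.9117897379, Sr = 87.9056125000,
    Y  = 88.9058403000, Zr = 89.9046977000, Nb = 92.9063730000,
    Mo = 97.9054048200, Ru = 101.9043441000, Rh = 102.9054980000,
    Pd = 105.9034804000, Ag = 106.9050916000, Cd = 113.9033650900,
    In = 114.9038787760, Sn = 119.9022016300, Sb = 120.9038120000,
    Te = 129.9062227480, I = 126.9044719000, Xe = 131.9041550856,
    Cs = 132.9054519610, Ba = 137.9052470000, W = 183.9509309200,
    Pt = 194.9647917000, Au = 196.9665687900, Hg = 201.9706434000,
    Pb = 207.9766525000
)

## Fundamental charge-carrier masses (Da), CODATA.
.PROTON_MASS <- 1.00727646688
.ELECTRON_MASS <- 0.00054857990907
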