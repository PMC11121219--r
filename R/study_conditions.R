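## Built-in generating parameters for the synthetic module: per-breed means
## and standard errors (n = 16 per breed) of the physicochemical attributes,
## the carcass traits (per breed x sex, n = 8 per cell) and the intramuscular
## fatty-acid profile of suckling-kid meat from the two PDO goat breeds the
## workflow targets ("Serrana", "Preta de Montesinho"). Standard deviations
## for sampling are recovered as SEM * sqrt(n).

#' Breed labels of the emulated study
#' @return Character vector of the two breed names.
#' @export
study_breeds <- function() c("Serrana", "Preta de Montesinho")

#' Per-breed physicochemical attribute parameters
#'
#' Mean per breed and the pooled standard error of the mean (SEM, n = 16
#' per breed) for each measured meat-quality attribute. `lower`/`upper`
#' are the physical truncation bounds used when sampling.
#'
#' @return Data frame: `attribute`, `Serrana`, `Preta de Montesinho`,
#'   `sem`, `lower`, `upper`.
#' @export
attribute_parameters <- function() {
  df <- read.csv(text = '
attribute,serrana,preta,sem,lower,upper
pH,5.98,5.88,0.041,5,7
WHC,12.93,19.23,1.222,0,100
SF,2.33,3.88,0.156,0.1,Inf
L_star,54.71,52.56,0.869,0,100
a_star,18.39,14.70,0.611,0.5,Inf
b_star,12.96,11.42,0.257,0.5,Inf
Moisture,75.80,74.78,0.530,0,100
Ash,1.20,1.22,0.086,0,100
Protein,21.06,21.66,0.254,0,100
IMF,1.20,1.81,0.162,0.05,100
', stringsAsFactors = FALSE)
  names(df)[2:3] <- study_breeds()
  df
}

#' Per-breed fatty-acid profile parameters
#'
#' Mean percentage of total fatty acids per breed with the pooled SEM
#' (n = 16 per breed) for every quantified fatty acid. Sampling truncates
#' at zero.
#'
#' @return Data frame: `fa`, `Serrana`, `Preta de Montesinho`, `sem`.
#' @export
fatty_acid_parameters <- function() {
  df <- read.csv(text = '
fa,serrana,preta,sem
C10:0,0.114,0.090,0.014
C12:0,0.483,0.424,0.038
C14:0,5.435,4.564,0.359
C14:1,0.206,0.176,0.026
C15:0,0.211,0.211,0.027
C15:1,0.163,0.121,0.011
C16:0,26.198,25.032,0.573
C16:1n-7,2.300,2.314,0.130
C17:0,0.765,0.738,0.043
C17:1n-7,0.592,0.585,0.032
C18:0,11.682,11.935,0.487
9t-C18:1,1.637,1.592,0.093
C18:1n-9,38.749,38.666,0.984
"9t,12t-C18:2",0.281,0.275,0.020
C18:2n-6,6.489,6.614,0.607
C20:0,0.045,0.027,0.007
C18:3n-6,0.066,0.069,0.010
C20:1n-9,0.439,1.048,0.085
C18:3n-3,0.665,0.679,0.042
C21:0,0.012,0.010,0.006
C20:2n-6,0.042,0.027,0.008
C22:0,0.169,0.237,0.046
C20:3n-6,0.141,0.198,0.029
C22:1n-9,0.015,0.023,0.008
C20:4n-6,2.339,2.387,0.335
C20:3n-3,0.044,0.004,0.022
C22:2n-6,0.000,0.002,0.000
C24:0,0.214,0.865,0.141
C24:1n-9,0.231,0.402,0.116
C22:6n-3,0.234,0.670,0.135
', stringsAsFactors = FALSE, check.names = FALSE)
  names(df)[2:3] <- study_breeds()
  df
}

#' Per-breed-and-sex carcass trait parameters
#'
#' Means per breed x sex cell (n = 8) with the pooled SEM for the carcass
#' traits: age at slaughter (days), daily gain (g/day), live weight at
#' slaughter (kg), cold carcass weight (kg) and dressing yield (%).
#'
#' @return Data frame: `trait`, `Serrana.M`, `Serrana.F`, `Preta.M`,
#'   `Preta.F`, `sem`.
#' @export
carcass_parameters <- function() {
  read.csv(text = '
trait,Serrana.M,Serrana.F,Preta.M,Preta.F,sem
age,72.4,73.6,73.1,67.0,5.012
dg,118.3,119.4,110.6,110.9,11.51
lws,10.9,10.8,10.2,9.2,0.559
ccw,5.8,6.0,5.7,5.1,0.325
yield,53.2,55.5,55.8,55.4,1.157
', stringsAsFactors = FALSE, check.names = FALSE)
}
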