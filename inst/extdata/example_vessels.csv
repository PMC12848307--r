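"vessel_id","timepoint","diameter_um","length_um","ec_count"
"v01","2dpf",7.95833417532511,59.9817266233467,NA
"v02","2dpf",7.91620791611067,60.8011297340623,NA
"v03","2dpf",6.98697498907027,58.10874859005,NA
"v01","3dpf",7.94282945252318,72.2314589957837,NA
"v02","3dpf",7.05452692679728,65.3983797898216,NA
"v03","3dpf",6.70212921323437,78.3079658324949,NA
"v01","4dpf",6.25982175896684,74.905678418572,NA
"v02","4dpf",6.82765018263586,90.4406682137155,NA
"v03","4dpf",6.64806164642757,83.9470941267001,NA
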