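# Published national projection of annual hip fracture counts in Pakistan,
# persons aged 50 years and older, with age- and sex-specific incidence held
# at its 2015 level and demography following the UN medium-fertility variant.
year,men,women
2015,12902,23622
2020,14885,27364
2030,19699,37948
2040,26943,54840
2050,36587,78233
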