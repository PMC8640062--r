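# Published aggregate results for the 31-city study (central and 95% CI),
# transcribed from the source study's abstract and results text. Used as
# inputs to arithmetic-consistency checks (NCD-other segregation, scenario
# percent change); deaths are cases/year among adults age > 25, losses in
# million US$ as of 2017.
quantity,central,low,high
ncd_lri_deaths_2017,80447,70094,89581
cod5_deaths_2017,72903,62514,82626
ncd_lri_deaths_2024,79633,70228,88859
loss_musd_2017,90185.6,88016.4,92411
loss_musd_2024,89558.7,87792.15,91363.3
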