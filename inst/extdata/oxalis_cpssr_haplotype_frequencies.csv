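population,region,n,122-121,121-122,121-120,120-119,122-120
Cyprus,invaded,NA,100.00,0,0,0,0
Lisbon,invaded,NA,100.00,0,0,0,0
Piombino (IT),invaded,NA,100.00,0,0,0,0
Giglio C. (IT),invaded,NA,90.00,10.00,0,0,0
Giglio A. (IT),invaded,NA,100.00,0,0,0,0
Calabria1 (IT),invaded,NA,100.00,0,0,0,0
Genova O. B. (IT),invaded,NA,63.63,36.36,0,0,0
Sestri (IT),invaded,NA,70.00,30.00,0,0,0
Imperia (IT),invaded,NA,76.92,7.69,7.69,0,7.69
Ittiri (IT),invaded,NA,100.00,0,0,0,0
Palermo O.B. (IT),invaded,NA,90.00,10.00,0,0,0
Ficarra (IT),invaded,NA,100.00,0,0,0,0
Capoliveri (IT),invaded,NA,75.00,8.33,8.33,8.33,0
Capraia (IT),invaded,NA,100.00,0,0,0,0
Cavo (IT),invaded,NA,80.00,10.00,10.00,0,0
Enfola (IT),invaded,NA,100.00,0,0,0,0
M. Campo-Lac. (IT),invaded,NA,100.00,0,0,0,0
Malta2,invaded,NA,66.66,16.66,0,16.66,0
S. Andrea (IT),invaded,NA,80.00,0,20.00,0,0
Kirstenbosch (SA),native,NA,100.00,0,0,0,0
Tanqua Karoo (SA),native,NA,66.66,0,0,0,33.33
Jacobsbaii (SA),native,NA,100.00,0,0,0,0
Calabria2 (IT),invaded,NA,100.00,0,0,0,0
Castiglioncello (IT),invaded,NA,70.00,20.00,10.00,0,0
Chiessi (IT),invaded,NA,66.66,6.66,6.66,13.33,6.66
Rodi Garganico (IT),invaded,NA,80.00,6.66,6.66,6.66,0
Stintino (IT),invaded,NA,86.66,0,6.66,6.66,0
Giannutri (IT),invaded,NA,100.00,0,0,0,0
Hanbury (IT),invaded,NA,40.00,40.00,0,0,20.00
Malta3,invaded,NA,93.33,0,0,6.66,0
Malta1,invaded,NA,62.50,37.50,0,0,0
Marocco,invaded,NA,90.00,0,0,0,10.00
Pianosa (IT),invaded,NA,92.30,0,0,7.69,0
Pollina (IT),invaded,NA,100.00,0,0,0,0
Rio Marina (IT),invaded,NA,73.33,13.33,13.33,0,0
Riomaggiore (IT),invaded,NA,100.00,0,0,0,0
Ventotene (IT),invaded,NA,100.00,0,0,0,0
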