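# srbcolumn embedded thermodynamic table, version 1 (25 C reference, I = 0)
# Reconstruction of a minteq-family aqueous model restricted to the components
# relevant to a neutralized-AMD sulfate-reducing column. log K are formation
# constants (species) from components, log Ksp are dissolution constants
# (minerals) written toward components. Stoichiometry syntax: "Comp:coef;Comp:coef";
# H2O is implicit (activity 1). Charges in elementary units, molar masses g/mol.
kind,name,charge,molar_mass,logk,stoichiometry
component,H,1,1.008,,
component,CO3,-2,60.009,,
component,SO4,-2,96.06,,
component,HS,-1,33.073,,
component,Ac,-1,59.044,,
component,EtOH,0,46.068,,
component,O2,0,31.998,,
component,Ca,2,40.078,,
component,Zn,2,65.38,,
component,Cu,2,63.546,,
component,Cd,2,112.414,,
component,Si,0,28.086,,
component,Na,1,22.990,,
component,Cl,-1,35.453,,
species,OH,-1,17.007,-13.997,H:-1
species,HCO3,-1,61.017,10.329,CO3:1;H:1
species,H2CO3,0,62.025,16.681,CO3:1;H:2
species,HSO4,-1,97.068,1.988,SO4:1;H:1
species,H2S,0,34.081,6.994,HS:1;H:1
species,HAc,0,60.052,4.757,Ac:1;H:1
species,CaHCO3,1,101.095,11.434,Ca:1;CO3:1;H:1
species,CaCO3aq,0,100.087,3.224,Ca:1;CO3:1
species,CaSO4aq,0,136.138,2.360,Ca:1;SO4:1
species,CaOH,1,57.085,-12.780,Ca:1;H:-1
species,ZnOH,1,82.387,-8.997,Zn:1;H:-1
species,ZnOH2aq,0,99.394,-17.794,Zn:1;H:-2
species,ZnCO3aq,0,125.389,5.300,Zn:1;CO3:1
species,ZnHCO3,1,126.397,12.429,Zn:1;CO3:1;H:1
species,ZnSO4aq,0,161.440,2.370,Zn:1;SO4:1
species,CuOH,1,80.553,-7.497,Cu:1;H:-1
species,CuOH2aq,0,97.560,-16.196,Cu:1;H:-2
species,CuCO3aq,0,123.555,6.730,Cu:1;CO3:1
species,CuHCO3,1,124.563,12.130,Cu:1;CO3:1;H:1
species,CuSO4aq,0,159.606,2.360,Cu:1;SO4:1
species,CdOH,1,129.421,-10.080,Cd:1;H:-1
species,CdCO3aq,0,172.423,4.360,Cd:1;CO3:1
species,CdHCO3,1,173.431,11.830,Cd:1;CO3:1;H:1
species,CdSO4aq,0,208.474,2.460,Cd:1;SO4:1
mineral,calcite,0,100.087,-8.480,Ca:1;CO3:1
mineral,smithsonite,0,125.389,-10.000,Zn:1;CO3:1
mineral,otavite,0,172.423,-12.100,Cd:1;CO3:1
mineral,malachite,0,221.116,-5.180,Cu:2;CO3:1;H:-2
mineral,sphalerite,0,97.445,-11.620,Zn:1;HS:1;H:-1
mineral,covellite,0,95.611,-22.270,Cu:1;HS:1;H:-1
mineral,greenockite,0,144.479,-14.360,Cd:1;HS:1;H:-1
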