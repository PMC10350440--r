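category,quantity,family,location,mean,sd
drinking_water,HI,lognormal,0,0.95,2.01
meat,HI,lognormal,0,1.14,1.12
cereal,HI,lognormal,0,1.69,2.38
beans,HI,lognormal,0,0.47,0.48
potatoes,HI,lognormal,0,0.25,0.24
solanaceous_fruit,HI,lognormal,0,1.39,1.96
vegetables,HI,lognormal,0,1.39,1.58
fruit,HI,lognormal,0,1.35,9.06
drinking_water,R,lognormal,0,3.58e-4,8.91e-4
meat,R,lognormal,0,3.31e-4,3.96e-4
cereal,R,lognormal,0,1.52e-4,7.52e-4
potatoes,R,lognormal,0,0.39e-4,0.64e-4
solanaceous_fruit,R,lognormal,0,2.56e-4,7.09e-4
vegetables,R,lognormal,0,0.27e-4,1.83e-4
fruit,R,lognormal,0,3.24e-4,40.50e-4
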