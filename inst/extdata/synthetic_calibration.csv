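concentration,replicate,area
1,1,25757.9
1,2,24779.9
1,3,25243.9
1,4,25380.5
1,5,25264.7
1,6,25008.1
2.5,1,64575.9
2.5,2,62534.7
2.5,3,65233.9
2.5,4,62574.6
2.5,5,64309.6
2.5,6,65584.7
5,1,121873.9
5,2,124609.7
5,3,124972.7
5,4,126910.1
5,5,124596.1
5,6,118823.3
10,1,238675.4
10,2,257316.9
10,3,249080.6
10,4,241842.4
10,5,249752.6
10,6,256774.9
20,1,520586.5
20,2,496929.1
20,3,498653.3
20,4,483860.3
20,5,505858.5
20,6,494851.3
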