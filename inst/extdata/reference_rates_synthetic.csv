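age_lo,age_hi,period_lo,period_hi,rate
0,5,1960,1970,0
5,10,1960,1970,0
10,15,1960,1970,0
15,20,1960,1970,0
20,25,1960,1970,4.9600764335193777
25,30,1960,1970,8.8927973181590456
30,35,1960,1970,15.743339014249129
35,40,1960,1970,27.27420529890323
40,45,1960,1970,45.606380951589088
45,50,1960,1970,72.262624343749025
50,55,1960,1970,106.38937079708525
55,60,1960,1970,143.61062920291477
60,65,1960,1970,177.73737565625098
65,70,1960,1970,204.3936190484109
70,75,1960,1970,222.72579470109679
75,80,1960,1970,234.25666098575087
80,85,1960,1970,241.10720268184096
0,5,1970,1980,0
5,10,1970,1980,0
10,15,1970,1980,0
15,20,1970,1980,0
20,25,1970,1980,5.1460792997763543
25,30,1970,1980,9.2262772175900096
30,35,1970,1980,16.333714227283473
35,40,1970,1980,28.296987997612103
40,45,1970,1980,47.316620237273689
45,50,1970,1980,74.972472756639618
50,55,1970,1980,110.37897220197596
55,60,1970,1980,148.99602779802407
60,65,1970,1980,184.40252724336042
65,70,1970,1980,212.05837976272633
70,75,1970,1980,231.07801200238794
75,80,1970,1980,243.04128577271655
80,85,1970,1980,250.14872278241
0,5,1980,1990,0
5,10,1980,1990,0
10,15,1980,1990,0
15,20,1980,1990,0
20,25,1980,1990,5.33208216603333
25,30,1980,1990,9.5597571170209736
30,35,1980,1990,16.924089440317815
35,40,1980,1990,29.319770696320973
40,45,1980,1990,49.026859522958269
45,50,1980,1990,77.682321169530184
50,55,1980,1990,114.36857360686665
55,60,1980,1990,154.38142639313335
60,65,1980,1990,191.06767883046982
65,70,1980,1990,219.72314047704174
70,75,1980,1990,239.43022930367903
75,80,1980,1990,251.82591055968217
80,85,1980,1990,259.19024288297902
0,5,1990,2000,0
5,10,1990,2000,0
10,15,1990,2000,0
15,20,1990,2000,0
20,25,1990,2000,5.5180850322903074
25,30,1990,2000,9.8932370164519376
30,35,1990,2000,17.51446465335216
35,40,1990,2000,30.342553395029849
40,45,1990,2000,50.737098808642855
45,50,1990,2000,80.392169582420777
50,55,1990,2000,118.35817501175735
55,60,1990,2000,159.76682498824269
60,65,1990,2000,197.73283041757921
65,70,1990,2000,227.38790119135717
70,75,1990,2000,247.78244660497018
75,80,1990,2000,260.61053534664791
80,85,1990,2000,268.23176298354809
0,5,2000,2010,0
5,10,2000,2010,0
10,15,2000,2010,0
15,20,2000,2010,0
20,25,2000,2010,5.704087898547284
25,30,2000,2010,10.226716915882902
30,35,2000,2010,18.104839866386495
35,40,2000,2010,31.365336093738712
40,45,2000,2010,52.447338094327442
45,50,2000,2010,83.102017995311357
50,55,2000,2010,122.34777641664805
55,60,2000,2010,165.15222358335197
60,65,2000,2010,204.39798200468863
65,70,2000,2010,235.05266190567255
70,75,2000,2010,256.13466390626127
75,80,2000,2010,269.3951601336135
80,85,2000,2010,277.27328308411711
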