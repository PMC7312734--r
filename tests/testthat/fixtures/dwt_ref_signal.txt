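4.96714153011232673e-01
-1.38264301171184656e-01
6.47688538100692490e-01
1.52302985640802535e+00
-2.34153374723335972e-01
-2.34136956949180547e-01
1.57921281550739145e+00
7.67434729152908779e-01
-4.69474385934952110e-01
5.42560043585964658e-01
-4.63417692812462256e-01
-4.65729753570256866e-01
2.41962271566034115e-01
-1.91328024465779789e+00
-1.72491783251303277e+00
-5.62287529240972694e-01
-1.01283112033442380e+00
3.14247332595273876e-01
-9.08024075521210894e-01
-1.41230370133529148e+00
1.46564876892155405e+00
-2.25776300486535658e-01
6.75282046879238373e-02
-1.42474818621345678e+00
-5.44382724525182660e-01
1.10922589709866085e-01
-1.15099357742230279e+00
3.75698018345671958e-01
-6.00638689918804980e-01
-2.91693749793276780e-01
-6.01706612229396920e-01
1.85227818450893778e+00
-1.34972247379339209e-02
-1.05771092895590035e+00
8.22544912103189030e-01
-1.22084364997102224e+00
2.08863595004755404e-01
-1.95967012387977557e+00
-1.32818604889843050e+00
1.96861235869123519e-01
7.38466579995410433e-01
1.71368281189970495e-01
-1.15648282388240528e-01
-3.01103695589288789e-01
-1.47852199036742737e+00
-7.19844208394708640e-01
-4.60638770959787502e-01
1.05712222621891572e+00
3.43618289568461410e-01
-1.76304015536273395e+00
3.24083969394795002e-01
-3.85082280416316536e-01
-6.76922000305958727e-01
6.11676288840867888e-01
1.03099952249595095e+00
9.31280119116198568e-01
-8.39217523222638540e-01
-3.09212375851214583e-01
3.31263431403563957e-01
9.75545127122359190e-01
-4.79174237845289952e-01
-1.85658976663817116e-01
-1.10633497400602820e+00
-1.19620662408067080e+00
8.12525822394198016e-01
1.35624002857082293e+00
-7.20101215803338468e-02
1.00353289789202416e+00
3.61636025047634146e-01
-6.45119754605124274e-01
3.61395605508413931e-01
1.53803656646596920e+00
-3.58260391099515380e-02
1.56464365581400622e+00
-2.61974510408974437e+00
8.21902504375223830e-01
8.70470682381712241e-02
-2.99007350465867461e-01
9.17607765355022975e-02
-1.98756891460089280e+00
-2.19671887837511931e-01
3.57112571511746413e-01
1.47789404474151609e+00
-5.18270218273647387e-01
-8.08493602893187613e-01
-5.01757043584536544e-01
9.15402117702074136e-01
3.28751109659684460e-01
-5.29760203767038806e-01
5.13267433113356097e-01
9.70775493480403873e-02
9.68644990532889216e-01
-7.02053093877352374e-01
-3.27662146597768211e-01
-3.92108153132157633e-01
-1.46351494813211858e+00
2.96120277064576054e-01
2.61055272179889331e-01
5.11345664246088977e-03
-2.34587133375146917e-01
-1.41537074205041424e+00
-4.20645322765359042e-01
-3.42714516526769486e-01
-8.02277269221618905e-01
-1.61285711666009135e-01
4.04050856814538395e-01
1.88618590121053020e+00
1.74577812831838958e-01
2.57550390722764366e-01
-7.44459157661672144e-02
-1.91877121529904149e+00
-2.65138754492168782e-02
6.02302099410264372e-02
2.46324211248528613e+00
-1.92360964781122523e-01
3.01547342333612467e-01
-3.47117697052433116e-02
-1.16867803761953204e+00
1.14282281451502055e+00
7.51933032686774139e-01
7.91031947043046912e-01
-9.09387454794738925e-01
1.40279431093609919e+00
-1.40185106279228089e+00
5.86857093800270291e-01
2.19045562580997855e+00
-9.90536325130688344e-01
-5.66297729602771915e-01
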