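>P001
ARLWPHEQELAELKHKKCSHLCRVPHVE
>P002
SKVKIHKPKAHRHKNLTWSLRCLRIPML
>P003
GQRSTLLPLKVQHKFQIGDILRLKHALE
>P004
YRNRKHKFQTFGLKYLRFDIECEVIGLL
>P005
SLRMTMKMRNAIILSEAFVMLQERWRVE
>P006
WRLAVHKHRKDALEKELFEHKLKIVKME
>P007
FLLVLHQGERVWLKRQTYFHLTQRFWLL
>P008
GQVPNHQCLVNVIKWEIHMLLEETMCIQ
>P009
FLRPQMKAKKENIQIEILLLRCQTCCIK
>P010
VQRAVILVQVYEIQRQTGIMRWLRELVR
>P011
PKKFPMRCETKQVLVKLRLMRWKIWVHR
>P012
HRTSRIECQVEPLRMKLNKVKNRKIWIL
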