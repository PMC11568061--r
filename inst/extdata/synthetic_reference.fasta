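>synthetic_MGL_reference synthetic methionine gamma-lyase reference (398 aa, YGC@114, KD@240)
RYFIAAEDQDDAINLRKSAATVNAEGFHPPSILHAYLVDSEGEELESVIMGMVAKPAGAE
VLDIGEDLIFMEVGIGRNPTIVDVMGEKGEAELDAGAFNLLGYAQYEININIFYGCQLVK
ASLDAKIGATGLAPTQAVRAPFSKKIQLKCGTSGAHRAVVALSGFTQANQEMLMDPRAVV
HENGRNDGLVQARPEPASLLLMYTGEDPRMDVATVQRNSEDDSHIVATKKETPDGGTSGK
DLGKSNKEPQLVGLLGDLGVTACLMIGIGQTNGADSPLKIILSEMRSTLHQSFLHIGLPA
DRKAGQKSVFEVDRNSVGAPGCEVQQERPTGTQNVYLRHGRPYYVVSRWMGNVLSLESFG
LLAEEEKELELQHLREKALDDDFLASFIILLLAEIGTN
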