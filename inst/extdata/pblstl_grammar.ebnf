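(* Concrete grammar of the PBLSTL specification language accepted by
   parse_pblstl(). Whitespace is insignificant; '#' starts a line comment. *)

specification   = statement , { statement } ;

statement       = "P" , prob-comparator , probability ,
                  "[" , formula , "]" ;
prob-comparator = "<" | "<=" | ">" | ">=" ;
probability     = number ;                     (* strictly inside (0, 1) *)

formula         = iff ;
iff             = implies , { "<=>" , implies } ;
implies         = or-expr , [ "=>" , implies ] ;
or-expr         = and-expr , { "V" , and-expr } ;
and-expr        = until-expr , { "^" , until-expr } ;
until-expr      = unary-formula , { "U" , bounds , unary-formula } ;
unary-formula   = "~" , unary-formula
                | "F" , bounds , unary-formula
                | "G" , bounds , unary-formula
                | "X" , "[" , integer , "]" , unary-formula
                | atom ;
atom            = "(" , formula , ")" | comparison ;
bounds          = "[" , number , "," , number , "]" ;   (* 0 <= a <= b *)

comparison      = numeric , comparator , numeric ;
comparator      = "<" | "<=" | "=" | ">=" | ">" ;

numeric         = number
                | "-" , numeric
                | "{" , identifier , "}"        (* numeric state variable *)
                | "d" , "(" , numeric , ")"     (* next-state difference *)
                | unary-fn  , "(" , numeric , ")"
                | binary-fn , "(" , numeric , "," , numeric , ")"
                | statistic
                | "(" , numeric , ")" ;
unary-fn        = "abs" | "ceil" | "floor" | "round" | "sign" | "sqrt"
                | "trunc" ;
binary-fn       = "add" | "subtract" | "multiply" | "divide" | "power"
                | "min" | "max" ;

statistic       = "count" , "(" , collection , ")"
                | reducer , "(" , collection , "," , measure , ")"
                | "percentile" , "(" , collection , "," , measure , "," ,
                  number , ")"
                | "covariance" , "(" , collection , "," , measure , "," ,
                  collection , "," , measure , ")" ;
reducer         = "mean" | "median" | "mode" | "min" | "max" | "sum"
                | "stdev" ;

collection      = "regions" | "clusters"
                | "filter" , "(" , collection , "," , constraint , ")" ;

(* Constraints range over the eleven spatial measures compared against
   constant numeric expressions; state variables and statistics are not
   permitted inside them. *)
constraint      = constraint , "<=>" , constraint
                | constraint , "=>" , constraint
                | constraint , "V" , constraint
                | constraint , "^" , constraint
                | "~" , constraint
                | "(" , constraint , ")"
                | measure , comparator , constant-numeric ;
measure         = "clusteredness" | "density" | "area" | "perimeter"
                | "distanceFromOrigin" | "angle" | "triangularMeasure"
                | "rectangularMeasure" | "circularMeasure" | "centroidX"
                | "centroidY" ;

number          = digit , { digit } , [ "." , digit , { digit } ] ;
integer         = digit , { digit } ;
identifier      = letter , { letter | digit | "_" } ;
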